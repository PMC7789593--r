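test_that("jaccard similarity is exact, symmetric and bounded", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 0)
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length mismatch")
  withr::with_seed(3, {
    for (i in 1:20) {
      u <- stats::rbinom(30, 1, 0.3)
      v <- stats::rbinom(30, 1, 0.3)
      j <- jaccard_similarity(u, v)
      expect_identical(j, jaccard_similarity(v, u))
      expect_true(j >= 0 && j <= 1)
    }
  })
})

test_that("TF feature vectors are the per-TF disjunction over columns", {
  sim <- informative_sim()
  fv <- tf_feature_vectors(sim$data)
  keys <- parse_evidence_keys(evidence_columns(sim$data))
  for (tf in unique(keys$tf)) {
    manual <- as.integer(rowSums(sim$data[keys$column[keys$tf == tf]]) > 0)
    expect_equal(fv[[tf]], manual)
  }
  # an all-zero TF maps to the zero vector
  d <- sim$data
  d[[evidence_key("Z", "H3K27ac", "up")]] <- 0L
  expect_equal(sum(tf_feature_vectors(d)$Z), 0)
})

test_that("distinct-TF selection uses the max Jaccard against the reference", {
  genes <- paste0("g", 1:8)
  ref <- tibble::tibble(gene = genes,
                        R1 = c(1, 1, 0, 0, 0, 0, 0, 0),
                        R2 = c(0, 0, 1, 1, 1, 0, 0, 0))
  fore <- tibble::tibble(gene = genes,
                         F1 = c(1, 1, 0, 0, 0, 0, 0, 0),  # identical to R1
                         F2 = c(0, 0, 0, 0, 0, 1, 1, 0),  # disjoint
                         F3 = c(1, 0, 0, 0, 0, 0, 0, 1),  # jac(R1) = 1/3
                         F4 = c(0, 0, 1, 1, 0, 0, 0, 1),  # jac(R2) = 1/2
                         F5 = c(0, 0, 0, 0, 0, 0, 0, 0))  # empty -> 0
  out <- select_distinct_tfs(fore, ref, cutoff = 0.4)
  expect_setequal(out$tf, c("F2", "F3", "F5"))
  expect_equal(out$max_similarity[out$tf == "F3"], 1 / 3)
  # a TF identical to a reference profile is excluded at any cutoff <= 1
  expect_false("F1" %in% select_distinct_tfs(fore, ref, cutoff = 1)$tf)
  empty <- fore["gene"]
  expect_equal(nrow(select_distinct_tfs(empty, ref, 0.2)), 0)
})

test_that("hypergeometric enrichment matches enumeration and simulation", {
  # both sets of size 5 drawn from 10, overlapping completely: 1/C(10,5)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_enrichment(0, 50, 80, 100), 1)
  # Monte-Carlo oracle on a small instance: draw the second set, count
  # overlaps with a fixed first set
  u <- 20; a <- 6; b <- 8; k <- 4
  p_exact <- hypergeometric_enrichment(k, a, b, u)
  withr::with_seed(8, {
    n_draw <- 20000
    hits <- vapply(seq_len(n_draw), function(i) {
      sum(sample.int(u, b) <= a) >= k
    }, logical(1))
  })
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(mean(hits) - p_exact), 3 * se + 1e-12)
  # the strictly-greater tail drops the boundary term
  expect_equal(hypergeometric_enrichment(k, a, b, u, strict = TRUE),
               p_exact - stats::dhyper(k, a, u - a, b))
})

test_that("permuted evidence destroys an informative signal", {
  sim <- informative_sim()
  nl <- shuffled_null(sim$data, n_perm = 20, seed = 3, lambda = 0.1,
                      restarts = 1)
  expect_gt(nl$observed_llr, max(nl$perm$llr))
  expect_gt(nl$z, 3)
  # reproducible given the seed
  nl2 <- shuffled_null(sim$data, n_perm = 20, seed = 3, lambda = 0.1,
                       restarts = 1)
  expect_identical(nl$perm, nl2$perm)
})

test_that("an all-zero evidence matrix has an exactly null permutation distribution", {
  d <- tibble::tibble(gene = paste0("g", 1:300),
                      pval = withr::with_seed(4, stats::runif(300)))
  d[[evidence_key("A", "ATAC", "present")]] <- 0L
  nl <- shuffled_null(d, n_perm = 5, seed = 1, restarts = 1)
  expect_true(all(abs(nl$perm$llr) < 1e-4))
})

test_that("cross-validation is seed-reproducible and validates its inputs", {
  sim <- informative_sim()
  ev <- sim$data[c("gene", evidence_columns(sim$data))]
  pv <- sim$data[c("gene", "pval")]
  cv1 <- cross_validate(list(d50k = ev), pv, n_repeats = 3,
                        lambda_grid = c(0.1, 1), seed = 5, restarts = 1)
  cv2 <- cross_validate(list(d50k = ev), pv, n_repeats = 3,
                        lambda_grid = c(0.1, 1), seed = 5, restarts = 1)
  expect_identical(cv1$results, cv2$results)
  expect_identical(nrow(cv1$results), 3L * 2L)

  bad <- ev[-1, ]
  expect_error(cross_validate(list(a = ev, b = bad), pv, n_repeats = 2),
               "gene universe")
  expect_error(cross_validate(list(a = ev), pv[-(1:5), ], n_repeats = 2),
               "universe")
})

test_that("held-out LLR distinguishes informative from shuffled evidence", {
  sim <- informative_sim()
  ev <- sim$data[c("gene", evidence_columns(sim$data))]
  pv <- sim$data[c("gene", "pval")]
  shuf <- ev
  withr::with_seed(99, {
    for (cl in evidence_columns(shuf)) {
      shuf[[cl]] <- shuf[[cl]][sample.int(nrow(shuf))]
    }
  })
  n_rep <- 10
  cv_real <- cross_validate(list(d = ev), pv, n_repeats = n_rep,
                            lambda_grid = 0.1, seed = 11, restarts = 1)
  cv_shuf <- cross_validate(list(d = shuf), pv, n_repeats = n_rep,
                            lambda_grid = 0.1, seed = 11, restarts = 1)
  wins <- sum(cv_real$results$test_llr > cv_shuf$results$test_llr)
  expect_gte(wins, 9)

  # on shuffled (null) evidence the mean held-out LLR is not significantly
  # positive
  tt <- stats::t.test(cv_shuf$results$test_llr, alternative = "greater")
  expect_gt(tt$p.value, 0.05)
})

test_that("validation-guided CV records one chosen pair per repeat", {
  sim <- informative_sim()
  ev <- sim$data[c("gene", evidence_columns(sim$data))]
  pv <- sim$data[c("gene", "pval")]
  cv <- cross_validate(list(d = ev), pv, fractions = c(0.72, 0.18, 0.10),
                       n_repeats = 2, lambda_grid = c(0.1, 1), seed = 2,
                       restarts = 1)
  expect_identical(nrow(cv$results), 2L)
  expect_true(all(cv$results$chosen))
  expect_true(all(cv$results$lambda %in% c(0.1, 1)))
})

test_that("top-rank frequency separates informative from empty targets", {
  sim <- informative_sim()
  genes <- sim$data$gene
  target <- sim$data[c("gene", evidence_key("TF01", "H3K27ac", c("down", "up")))]
  pool <- tibble::tibble(gene = genes)
  withr::with_seed(21, {
    for (tf in sprintf("K%02d", 1:25)) {
      pool[[evidence_key(tf, "H3K27ac", "down")]] <- 0L  # inert distractors
    }
  })
  pv <- sim$data[c("gene", "pval")]
  res <- top_rank_frequency(target, pool, pv, n_iter = 3, pool_size = 19,
                            seed = 1, restarts = 1)
  expect_equal(res$frequency, 1)
  expect_identical(nrow(res$panels), 3L)

  res1 <- top_rank_frequency(target, pool, pv, n_iter = 1, pool_size = 19,
                             seed = 1, restarts = 1)
  expect_true(res1$frequency %in% c(0, 1))
  expect_error(top_rank_frequency(target, pool, pv, pool_size = 40),
               "need 40")
})
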