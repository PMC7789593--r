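#' Cross-validation over distance and regularization hyperparameters
#'
#' Two schemes are supported via `fractions`:
#' * hyperparameter mode, e.g. `c(0.8, 0, 0.2)`: every repeat fits on the
#'   training genes for every (distance, lambda) pair and records the
#'   held-out test LLR; the best pair maximizes the mean summed up+down test
#'   LLR across repeats.
#' * strategy-comparison mode, e.g. `c(0.72, 0.18, 0.10)`: the validation
#'   set picks (distance, lambda) per repeat and only the chosen pair's test
#'   LLR is recorded, so strategies can be compared pairwise per repeat.
#'
#' The held-out LLR is `loglik(test; fitted model) - loglik(test; fitted
#' null)`, both evaluated at parameters trained on the training genes.
#'
#' @param matrices_by_d Named list of model frames (evidence only, `gene` +
#'   columns), one per candidate distance; all must share the gene universe.
#' @param pvals_up,pvals_down Tibbles `gene`, `pval` from
#'   [transform_de_pvalues()]; `pvals_down = NULL` runs a single analysis.
#' @param fractions Train/validation/test proportions summing to 1
#'   (validation may be 0).
#' @param n_repeats Number of random partitions.
#' @param lambda_grid Candidate L2 coefficients; default `c(0.01, 0.1, 1, 10)`.
#' @param seed Integer seed; partitions are reproducible given the seed.
#' @param variant,restarts,max_iters Passed to [pgm_fit()].
#' @return An object of class `pgm_cv`: list with `results` (one row per
#'   repeat x distance x lambda x analysis actually fitted: `repeat_id`, `d`,
#'   `lambda`, `analysis`, `test_llr`, `chosen`), `best` (the selected
#'   `(d, lambda)` and its mean summed test LLR), `fractions`, `seed`.
#' @export
cross_validate <- function(matrices_by_d, pvals_up, pvals_down = NULL,
                           fractions = c(0.8, 0, 0.2), n_repeats = 10,
                           lambda_grid = c(0.01, 0.1, 1, 10), seed = 1L,
                           variant = "pgenmi", restarts = 2, max_iters = 300) {
  stopifnot(is.list(matrices_by_d), !is.null(names(matrices_by_d)),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            fractions[1] > 0, fractions[3] > 0, n_repeats >= 1)
  genes <- matrices_by_d[[1]]$gene
  for (m in matrices_by_d) {
    if (!identical(sort(m$gene), sort(genes))) {
      stop("all evidence matrices must share the same gene universe")
    }
  }
  analyses <- list(up = pvals_up)
  if (!is.null(pvals_down)) analyses$down <- pvals_down
  for (pv in analyses) {
    if (!setequal(pv$gene, genes)) {
      stop("p-value gene universe differs from the evidence matrices")
    }
  }
  use_validation <- fractions[2] > 0
  n <- length(genes)

  splits <- withr::with_seed(seed, lapply(seq_len(n_repeats), function(i) {
    idx <- sample.int(n)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    list(train = genes[idx[seq_len(n_tr)]],
         validation = genes[idx[n_tr + seq_len(n_va)]],
         test = genes[idx[(n_tr + n_va + 1):n]])
  }))

  eval_split <- function(frame, pvals, train_genes, held_genes) {
    joined <- dplyr::inner_join(frame, pvals, by = "gene")
    tr <- joined[joined$gene %in% train_genes, ]
    he <- joined[joined$gene %in% held_genes, ]
    function(lambda) {
      fit <- pgm_fit(tr, variant = variant, lambda = lambda,
                     restarts = restarts, seed = seed, max_iters = max_iters)
      Xh <- as_evidence_matrix(he)[, fit$keys$column, drop = FALSE]
      ll_alt <- loglik_at(fit, Xh, he$pval)
      null_par <- pgm_params(fit$null$w0, stats::setNames(numeric(0), character(0)),
                             fit$null$alpha)
      ll_null <- sum(gene_log_density(null_par, he$pval,
                                      matrix(0, nrow(he), 0)))
      list(fit = fit, llr = ll_alt - ll_null)
    }
  }

  rows <- list()
  for (i in seq_len(n_repeats)) {
    sp <- splits[[i]]
    grid <- tidyr::expand_grid(d = names(matrices_by_d), lambda = lambda_grid)
    scored <- purrr::pmap(grid, function(d, lambda) {
      purrr::imap(analyses, function(pv, nm) {
        held <- if (use_validation) sp$validation else sp$test
        eval_split(matrices_by_d[[d]], pv, sp$train, held)(lambda)
      })
    })
    summed <- vapply(scored, function(s) sum(vapply(s, `[[`, numeric(1), "llr")),
                     numeric(1))
    if (use_validation) {
      best_j <- which.max(summed)
      d_star <- grid$d[best_j]; l_star <- grid$lambda[best_j]
      for (nm in names(analyses)) {
        fit <- scored[[best_j]][[nm]]$fit
        joined <- dplyr::inner_join(matrices_by_d[[d_star]], analyses[[nm]],
                                    by = "gene")
        te <- joined[joined$gene %in% sp$test, ]
        Xt <- as_evidence_matrix(te)[, fit$keys$column, drop = FALSE]
        null_par <- pgm_params(fit$null$w0,
                               stats::setNames(numeric(0), character(0)),
                               fit$null$alpha)
        llr <- loglik_at(fit, Xt, te$pval) -
          sum(gene_log_density(null_par, te$pval, matrix(0, nrow(te), 0)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          repeat_id = i, d = d_star, lambda = l_star, analysis = nm,
          test_llr = llr, chosen = TRUE)
      }
    } else {
      for (j in seq_len(nrow(grid))) {
        for (nm in names(analyses)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            repeat_id = i, d = grid$d[j], lambda = grid$lambda[j],
            analysis = nm, test_llr = scored[[j]][[nm]]$llr, chosen = FALSE)
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows)

  best <- if (use_validation) {
    results |>
      dplyr::summarise(mean_sum_test_llr = mean(.data$test_llr) *
                         length(analyses), .by = character(0)) |>
      dplyr::mutate(d = NA_character_, lambda = NA_real_)
  } else {
    results |>
      dplyr::summarise(sum_llr = sum(.data$test_llr),
                       .by = c("repeat_id", "d", "lambda")) |>
      dplyr::summarise(mean_sum_test_llr = mean(.data$sum_llr),
                       .by = c("d", "lambda")) |>
      dplyr::arrange(dplyr::desc(.data$mean_sum_test_llr)) |>
      dplyr::slice_head(n = 1)
  }
  structure(list(results = results, best = best, fractions = fractions,
                 n_repeats = n_repeats, seed = seed),
            class = "pgm_cv")
}

#' @export
print.pgm_cv <- function(x, ...) {
  cat(sprintf("<pgm_cv> %d repeats, fractions %s\n", x$n_repeats,
              paste(x$fractions, collapse = "/")))
  print(x$best)
  invisible(x)
}

#' Permutation null for the full-data log-likelihood ratio
#'
#' Each permutation independently reassigns every evidence column's bits
#' across genes (preserving the column marginals), refits the model on the
#' full gene set, and records its LLR; the observed LLR is compared with the
#' permuted distribution via a z-score.
#'
#' @param data Model frame (`gene`, `pval`, evidence columns).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param fit Optional fit of `data` itself; computed if missing.
#' @param lambda,variant,restarts,max_iters Passed to [pgm_fit()] for each
#'   permutation (and for the observed fit when not supplied).
#' @return An object of class `pgm_null`: list with `perm` (tibble `perm`,
#'   `llr`), `observed_llr`, `mean`, `sd`, `z`.
#' @export
shuffled_null <- function(data, n_perm = 100, seed = 1L, fit = NULL,
                          lambda = 0.1, variant = "pgenmi", restarts = 1,
                          max_iters = 300) {
  stopifnot(n_perm >= 1)
  check_model_frame(data)
  if (is.null(fit)) {
    fit <- pgm_fit(data, variant = variant, lambda = lambda,
                   restarts = restarts, seed = seed, max_iters = max_iters)
  }
  cols <- evidence_columns(data)
  null_fit <- pgm_fit(data[c("gene", "pval")], variant = "null", lambda = 0,
                      restarts = restarts, seed = seed, max_iters = max_iters)
  llrs <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- data
    for (cl in cols) perm[[cl]] <- perm[[cl]][sample.int(nrow(perm))]
    pgm_fit(perm, variant = variant, lambda = lambda, restarts = restarts,
            seed = seed, max_iters = max_iters, null_fit = null_fit)$llr
  }, numeric(1)))
  m <- mean(llrs); s <- stats::sd(llrs)
  structure(list(
    perm = tibble::tibble(perm = seq_len(n_perm), llr = llrs),
    observed_llr = fit$llr, mean = m, sd = s,
    z = if (n_perm > 1 && s > 0) (fit$llr - m) / s else NA_real_
  ), class = "pgm_null")
}

#' @export
print.pgm_null <- function(x, ...) {
  cat(sprintf("<pgm_null> %d permutations: mean=%.2f sd=%.2f observed=%.2f z=%.2f\n",
              nrow(x$perm), x$mean, x$sd, x$observed_llr, x$z))
  invisible(x)
}

#' Per-TF binary feature vectors over genes
#'
#' Collapses each TF's evidence columns to a single gene-length bit vector by
#' disjunction (OR), the feature representation used to compare binding
#' profiles across cell lines.
#'
#' @param data Model frame with evidence columns.
#' @return A tibble with `gene` and one 0/1 column per TF (named by TF).
#' @export
tf_feature_vectors <- function(data) {
  check_model_frame(data, need_pval = FALSE)
  keys <- parse_evidence_keys(evidence_columns(data))
  out <- tibble::tibble(gene = data$gene)
  for (tf in sort(unique(keys$tf))) {
    out[[tf]] <- as.integer(rowSums(data[keys$column[keys$tf == tf]]) > 0)
  }
  out
}

#' Jaccard similarity of two binary vectors
#'
#' `|u AND v| / |u OR v|`; defined as 0 when both vectors are all-zero.
#'
#' @param u,v Equal-length binary (0/1 or logical) vectors.
#' @return A number in \[0, 1\].
#' @export
jaccard_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop(sprintf("length mismatch: %d vs %d", length(u), length(v)))
  }
  u <- as.logical(u); v <- as.logical(v)
  denom <- sum(u | v)
  if (denom == 0) return(0)
  sum(u & v) / denom
}

#' Select foreign TF profiles dissimilar to a reference panel
#'
#' For each foreign TF, its similarity score is the maximum Jaccard
#' similarity between its feature vector and any reference TF's feature
#' vector; TFs scoring below `cutoff` are returned. This implements the
#' "distinct profile" selection used to build unrelated-TF control panels.
#'
#' @param foreign_features,reference_features Tibbles from
#'   [tf_feature_vectors()], on the same gene universe (matched by `gene`).
#' @param cutoff Similarity threshold (default 0.2); strictly-less survives.
#' @return A tibble with `tf` and `max_similarity` for the selected TFs,
#'   sorted by similarity.
#' @export
select_distinct_tfs <- function(foreign_features, reference_features,
                                cutoff = 0.2) {
  stopifnot("gene" %in% names(foreign_features),
            "gene" %in% names(reference_features))
  ref <- reference_features[match(foreign_features$gene, reference_features$gene), ]
  if (anyNA(ref$gene)) stop("feature tibbles must share the gene universe")
  f_tfs <- setdiff(names(foreign_features), "gene")
  r_tfs <- setdiff(names(ref), "gene")
  scores <- purrr::map_dbl(f_tfs, function(ft) {
    max(purrr::map_dbl(r_tfs, function(rt) {
      jaccard_similarity(foreign_features[[ft]], ref[[rt]])
    }))
  })
  tibble::tibble(tf = f_tfs, max_similarity = scores) |>
    dplyr::filter(.data$max_similarity < cutoff) |>
    dplyr::arrange(.data$max_similarity, .data$tf)
}

#' Frequency with which a target TF outranks sampled distractor profiles
#'
#' Repeatedly trains a model on the target TF's evidence columns plus the
#' columns of `pool_size` distractor TFs sampled from a pool, and counts how
#' often the target attains the top contribution score ([tf_delta_llr()]).
#'
#' @param target_data Model frame holding the target TF's evidence columns.
#' @param distractor_data Model frame holding the distractor pool's columns
#'   (same gene universe and order as `target_data`).
#' @param pvals Tibble `gene`, `pval`.
#' @param n_iter Number of sampled panels.
#' @param pool_size Distractors per panel (default 19, for 20-TF panels).
#' @param seed Integer seed.
#' @param lambda,restarts,max_iters Passed to [pgm_fit()].
#' @return A list with `frequency` (fraction of panels topped by the target),
#'   `mean_llr` (mean model LLR across panels), and `panels` (per-iteration
#'   tibble: `iter`, `llr`, `target_top`, `target_delta_llr`).
#' @export
top_rank_frequency <- function(target_data, distractor_data, pvals,
                               n_iter = 20, pool_size = 19, seed = 1L,
                               lambda = 0.1, restarts = 1, max_iters = 300) {
  stopifnot(identical(target_data$gene, distractor_data$gene), n_iter >= 1)
  target_tf <- unique(parse_evidence_keys(evidence_columns(target_data))$tf)
  if (length(target_tf) != 1) stop("target_data must hold exactly one TF")
  pool_keys <- parse_evidence_keys(evidence_columns(distractor_data))
  pool_tfs <- setdiff(unique(pool_keys$tf), target_tf)
  if (length(pool_tfs) < pool_size) {
    stop("distractor pool has only ", length(pool_tfs), " TFs; need ", pool_size)
  }
  null_fit <- pgm_fit(dplyr::inner_join(target_data["gene"], pvals, by = "gene"),
                      variant = "null", lambda = 0, seed = seed,
                      restarts = restarts, max_iters = max_iters)
  rows <- withr::with_seed(seed, purrr::map_dfr(seq_len(n_iter), function(i) {
    picked <- sample(pool_tfs, pool_size)
    cols <- pool_keys$column[pool_keys$tf %in% picked]
    frame <- dplyr::bind_cols(target_data, distractor_data[cols]) |>
      dplyr::inner_join(pvals, by = "gene")
    fit <- pgm_fit(frame, lambda = lambda, restarts = restarts, seed = seed,
                   max_iters = max_iters, null_fit = null_fit)
    ranks <- tf_delta_llr(fit, frame)
    tibble::tibble(
      iter = i, llr = fit$llr,
      target_top = ranks$tf[1] == target_tf,
      target_delta_llr = ranks$delta_llr[ranks$tf == target_tf]
    )
  }))
  list(frequency = mean(rows$target_top), mean_llr = mean(rows$llr),
       panels = rows)
}

#' Exact hypergeometric enrichment of a set overlap
#'
#' Upper-tail probability that two sets of the given sizes, drawn from a
#' common universe, overlap at least (`strict = FALSE`, the default) or
#' strictly more than (`strict = TRUE`) the observed count. Some published
#' overlap analyses report the strictly-greater tail; both are exposed.
#'
#' @param overlap Observed overlap count.
#' @param set_a_size,set_b_size Sizes of the two sets.
#' @param universe Size of the gene universe the sets are drawn from.
#' @param strict Use P(X > overlap) instead of P(X >= overlap).
#' @return The tail probability.
#' @examples
#' hypergeometric_enrichment(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometric_enrichment <- function(overlap, set_a_size, set_b_size,
                                      universe, strict = FALSE) {
  stopifnot(overlap >= 0, overlap <= min(set_a_size, set_b_size),
            set_a_size <= universe, set_b_size <= universe)
  k <- if (strict) overlap else overlap - 1
  stats::phyper(k, set_a_size, universe - set_a_size, set_b_size,
                lower.tail = FALSE)
}
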