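pk <- function(start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end)
}
no_pk <- pk(integer(0), integer(0))

test_that("dynamic marks require replicate consistency and stage exclusivity", {
  # present in both early replicates, absent late: a "down" interval
  dyn <- call_dynamic_marks(pk(100, 200), pk(150, 250), no_pk, no_pk)
  expect_equal(nrow(dyn$down), 1)
  expect_equal(dyn$down$start, 100)       # rep1 coordinates retained
  expect_equal(nrow(dyn$up), 0)

  # present in early rep1 only: replicate-inconsistent, emitted nowhere
  dyn2 <- call_dynamic_marks(pk(100, 200), no_pk, no_pk, no_pk)
  expect_equal(nrow(dyn2$down) + nrow(dyn2$up), 0)

  # a single shared base with the other stage kills dynamic status
  dyn3 <- call_dynamic_marks(pk(100, 200), pk(100, 200), pk(199, 300), no_pk)
  expect_equal(nrow(dyn3$down), 0)
  # ... and one base short of overlap does not
  dyn4 <- call_dynamic_marks(pk(100, 200), pk(100, 200), pk(200, 300), no_pk)
  expect_equal(nrow(dyn4$down), 1)

  marked <- dplyr::mutate(pk(1, 5), mark = "H3K27ac")
  other <- dplyr::mutate(pk(1, 5), mark = "H3K4me1")
  expect_error(call_dynamic_marks(marked, other, no_pk, no_pk), "mixed mark")
})

test_that("gene windows are half-open and TSS-centred", {
  genes <- tibble::tibble(gene = "g1", chrom = "chr1", strand = "+",
                          tss = 10000L)
  d <- 1000
  dyn <- list(M = list(down = pk(0, 1e6), up = no_pk))
  at <- function(s, e) {
    m <- suppressMessages(
      build_diffmark(list(T1 = pk(s, e)), dyn, genes, d))
    sum(as_evidence_matrix(m))
  }
  expect_equal(at(10000 + d, 10000 + d + 50), 0)      # first base outside
  expect_equal(at(10000 + d - 1, 10000 + d + 50), 1)  # last base inside
  expect_equal(at(10000 - d - 50, 10000 - d), 0)      # ends at window start
  expect_equal(at(10000 - d - 50, 10000 - d + 1), 1)
})

fx <- simulate_genomic_fixture(n_genes = 12, n_tfs = 3, seed = 2)
dyn_fx <- lapply(fx$marks, function(m) {
  call_dynamic_marks(m$early$rep1, m$early$rep2, m$late$rep1, m$late$rep2)
})

test_that("all six strategies reproduce the brute-force golden matrices", {
  dm <- suppressMessages(
    build_diffmark(fx$tf_peaks, dyn_fx, fx$genes, fx$distance))
  built <- list(
    DiffMark = dm,
    DiffMarkAggr = build_diffmarkaggr(dm),
    PresMark = build_presmark(fx$tf_peaks,
                              lapply(fx$marks, function(m) c(m$early, m$late)),
                              fx$genes, fx$distance),
    DiffAcc = suppressMessages(
      build_diffacc(fx$tf_peaks, fx$atac_early, fx$atac_late, fx$genes,
                    fx$distance)),
    PresAcc = build_presacc(fx$tf_peaks, fx$atac_early, fx$atac_late,
                            fx$genes, fx$distance),
    TFBSonly = build_tfbs_only(fx$tf_peaks, fx$genes, fx$distance)
  )
  for (s in names(built)) {
    expect_identical(as.data.frame(built[[s]]),
                     as.data.frame(fx$expected[[s]]), label = s)
  }
  # the fixture exercises the direction-conflict path
  expect_message(build_diffmark(fx$tf_peaks, dyn_fx, fx$genes, fx$distance),
                 "conflict")
})

test_that("direction exclusivity holds after conflict resolution", {
  dm <- suppressMessages(
    build_diffmark(fx$tf_peaks, dyn_fx, fx$genes, fx$distance))
  keys <- parse_evidence_keys(evidence_columns(dm))
  pairs <- unique(keys[c("tf", "mark")])
  for (i in seq_len(nrow(pairs))) {
    up_col <- dm[[evidence_key(pairs$tf[i], pairs$mark[i], "up")]]
    dn_col <- dm[[evidence_key(pairs$tf[i], pairs$mark[i], "down")]]
    expect_true(all(up_col + dn_col <= 1))
  }
})

test_that("pre-conflict bits are monotone in the window distance", {
  prev <- NULL
  for (d in c(1000, 5000, 20000, 60000)) {
    raw <- suppressMessages(
      build_diffmark(fx$tf_peaks, dyn_fx, fx$genes, d,
                     resolve_conflicts = FALSE))
    cur <- as_evidence_matrix(raw)
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("column counts per strategy match the evidence layout", {
  n_tfs <- length(fx$tf_peaks)
  counts <- c(DiffMark = 8, DiffMarkAggr = 2, PresMark = 4, DiffAcc = 2,
              PresAcc = 1, TFBSonly = 1)
  for (s in names(counts)) {
    expect_length(evidence_columns(fx$expected[[s]]), counts[[s]] * n_tfs)
  }
})

test_that("aggregation is the per-direction OR of mark columns", {
  withr::with_seed(5, {
    n <- 50
    dm <- tibble::tibble(gene = paste0("g", 1:n))
    for (tf in sprintf("T%02d", 1:20)) {
      for (mk in c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3")) {
        for (dir in c("down", "up")) {
          dm[[evidence_key(tf, mk, dir)]] <- stats::rbinom(n, 1, 0.2)
        }
      }
    }
  })
  ag <- build_diffmarkaggr(dm)
  expect_length(evidence_columns(ag), 40)
  keys <- parse_evidence_keys(evidence_columns(dm))
  for (tf in unique(keys$tf)) {
    for (dir in c("down", "up")) {
      cols <- keys$column[keys$tf == tf & keys$direction == dir]
      manual <- apply(dm[cols], 1, function(r) as.integer(any(r == 1)))
      expect_equal(ag[[evidence_key(tf, "any", dir)]], manual)
    }
  }
})

test_that("degenerate inputs are reported", {
  genes0 <- tibble::tibble(gene = character(), chrom = character(),
                           strand = character(), tss = integer())
  expect_error(build_tfbs_only(list(A = pk(1, 10)), genes0, 100),
               "empty gene list")
  genes <- tibble::tibble(gene = "g1", chrom = "chr1", strand = "+", tss = 500L)
  expect_warning(
    m <- build_diffmark(list(A = no_pk),
                        list(M = list(down = pk(1, 10), up = no_pk)),
                        genes, 100),
    "no peaks")
  expect_equal(sum(as_evidence_matrix(m)), 0)
  expect_error(build_tfbs_only(list(A = pk(1, 10, chrom = "chrX")),
                               dplyr::mutate(genes, chrom = "chr7"), 100),
               "no chromosome shared")
  expect_error(
    build_tfbs_only(list(A = pk(1, 10, chrom = "9")),
                    dplyr::mutate(genes, chrom = "chr9"), 100),
    NA)  # "9" vs "chr9" harmonized by prefix normalization
  expect_equal(sum(as_evidence_matrix(
    build_tfbs_only(list(A = pk(400, 600, chrom = "9")),
                    dplyr::mutate(genes, chrom = "chr9"), 200))), 1)
})
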