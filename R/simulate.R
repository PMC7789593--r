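#' Simulate a dataset from the generative model
#'
#' Draws binary evidence `r_gk ~ Bernoulli(evidence_density)` independently
#' per (gene, column), computes the logistic prior `pi_g` from the true
#' parameters, draws the latent indicator `Z_g ~ Bernoulli(pi_g)`, and draws
#' the p-value from Uniform(0,1) when `Z_g = 0` and Beta(alpha, 1) when
#' `Z_g = 1`. Fully deterministic given `seed`.
#'
#' With `correlated = TRUE`, evidence columns share a per-gene latent
#' "accessibility" factor: open genes (half of them) receive bits at
#' `1.8 * density` and closed genes at `0.2 * density`, preserving the
#' marginal density while inducing the positive column correlation seen for
#' co-localized binding in real data.
#'
#' @param n_genes,n_tfs Dataset dimensions.
#' @param mark_changes Character vector of mark-change labels; the default is
#'   the four histone marks crossed with the two directions (8 labels), giving
#'   `8 * n_tfs` evidence columns.
#' @param evidence_density Per-column Bernoulli rate in (0, 1).
#' @param true_w0 Intercept of the generative logistic prior.
#' @param true_w Column weights: a single number (recycled), a vector of
#'   length `n_tfs * length(mark_changes)`, or NULL to draw uniformly from
#'   `weight_range`.
#' @param true_alpha Generative beta shape in (0, 1].
#' @param weight_range Range for randomly drawn weights when `true_w = NULL`.
#' @param seed Integer seed.
#' @param correlated Induce correlated evidence columns (see Details).
#' @return A list of class `pgm_sim`: `data` (model frame `gene`, `pval`,
#'   evidence columns), `truth` (tibble `gene`, `z`, `prior`), `params` (the
#'   generative [pgm_params()]), and the echoed simulation settings.
#' @export
simulate_dataset <- function(n_genes, n_tfs = 20,
                             mark_changes = default_mark_changes(),
                             evidence_density = 0.05,
                             true_w0 = -2, true_w = NULL, true_alpha = 0.2,
                             weight_range = c(-3, 3), seed = 1L,
                             correlated = FALSE) {
  if (evidence_density <= 0 || evidence_density >= 1) {
    stop("`evidence_density` must lie strictly between 0 and 1")
  }
  if (true_alpha <= 0 || true_alpha > 1) stop("`true_alpha` must lie in (0, 1]")
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  labs <- strsplit(mark_changes, "-", fixed = TRUE)
  cols <- unlist(lapply(tfs, function(tf) {
    vapply(labs, function(l) {
      evidence_key(tf, l[1], if (length(l) > 1) l[2] else "present")
    }, character(1))
  }))
  k <- length(cols)

  withr::with_seed(seed, {
    if (is.null(true_w)) {
      true_w <- stats::runif(k, weight_range[1], weight_range[2])
    } else if (length(true_w) == 1) {
      true_w <- rep(true_w, k)
    } else if (length(true_w) != k) {
      stop(sprintf("`true_w` has length %d; expected %d (or 1)",
                   length(true_w), k))
    }
    if (correlated) {
      open <- stats::rbinom(n_genes, 1, 0.5)
      rate <- ifelse(open == 1, pmin(0.999, 1.8 * evidence_density),
                     0.2 * evidence_density)
      X <- matrix(stats::rbinom(n_genes * k, 1, rep(rate, k)), nrow = n_genes)
    } else {
      X <- matrix(stats::rbinom(n_genes * k, 1, evidence_density),
                  nrow = n_genes)
    }
    colnames(X) <- cols
    pi_g <- stats::plogis(true_w0 + drop(X %*% true_w))
    z <- stats::rbinom(n_genes, 1, pi_g)
    p <- stats::runif(n_genes)
    # Beta(alpha, 1) via inverse CDF: U^(1/alpha)
    p[z == 1] <- p[z == 1]^(1 / true_alpha)
    p <- pmax(p, 1e-12)
  })

  genes <- sprintf("g%05d", seq_len(n_genes))
  data <- dplyr::bind_cols(
    tibble::tibble(gene = genes, pval = p),
    tibble::as_tibble(as.data.frame(X, check.names = FALSE))
  )
  structure(list(
    data = data,
    truth = tibble::tibble(gene = genes, z = z, prior = pi_g),
    params = pgm_params(true_w0, stats::setNames(true_w, cols), true_alpha),
    n_genes = n_genes, n_tfs = n_tfs, mark_changes = mark_changes,
    evidence_density = evidence_density, seed = seed, correlated = correlated
  ), class = "pgm_sim")
}

#' Default mark-change labels: four histone marks x two directions
#' @return Character vector of 8 labels like `"H3K27ac-up"`.
#' @export
default_mark_changes <- function() {
  as.vector(outer(c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3"),
                  c("down", "up"), paste, sep = "-"))
}

#' Generate a toy genomic fixture with known expected evidence
#'
#' Writes small BED / narrowPeak / annotation files on a fake single
#' chromosome (`chrS`), placing peaks so that each pattern the evidence
#' builder must handle occurs at least once: replicate-inconsistent peaks,
#' cross-stage overlaps (killing dynamic status), window-boundary binding
#' sites, and direction conflicts. Expected matrices for all six strategies
#' are computed by an independent brute-force all-pairs interval scan (plain
#' loops, no interval library) so they can serve as an oracle for the
#' builder.
#'
#' @param n_genes Number of genes (<= 100).
#' @param n_tfs Number of TFs.
#' @param seed Integer seed for the randomized portion of peak placement.
#' @param dir Output directory for the files (created if needed); `NULL`
#'   skips writing.
#' @param distance Gene-window half-width used for the expected matrices.
#' @return A list: `genes`, `tf_peaks`, `marks` (per-mark stage/replicate
#'   peaks), `atac_early`, `atac_late`, `expected` (list of model frames per
#'   strategy), `paths` (written files, if `dir` given), `distance`.
#' @export
simulate_genomic_fixture <- function(n_genes = 12, n_tfs = 3, seed = 1L,
                                     dir = NULL, distance = 5000) {
  stopifnot(n_genes >= 6, n_genes <= 100, n_tfs >= 2)
  spacing <- 50000L
  genes <- tibble::tibble(
    gene = sprintf("gene%03d", seq_len(n_genes)),
    chrom = "chrS",
    strand = rep(c("+", "-"), length.out = n_genes),
    tss = spacing * seq_len(n_genes)
  )
  genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 2000L)
  genes$end <- genes$start + 2000L

  mark_names <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3")
  tfs <- sprintf("TF%02d", seq_len(n_tfs))

  rnd <- withr::with_seed(seed, {
    list(
      tf_offsets = matrix(sample(-4000:4000, n_tfs * n_genes, replace = TRUE),
                          nrow = n_tfs),
      keep = matrix(stats::rbinom(n_tfs * n_genes, 1, 0.6), nrow = n_tfs)
    )
  })

  # TF peaks: ~60% of genes get a 400 bp TFBS near the TSS; gene 1 hosts the
  # window-boundary cases (one TFBS starting exactly at tss + d, one ending
  # exactly at tss + d).
  tf_peaks <- stats::setNames(lapply(seq_len(n_tfs), function(t) {
    rows <- lapply(seq_len(n_genes), function(g) {
      if (rnd$keep[t, g] == 1) {
        s <- genes$tss[g] + rnd$tf_offsets[t, g]
        tibble::tibble(chrom = "chrS", start = s, end = s + 400L)
      }
    })
    extra <- if (t == 1) {
      tibble::tibble(chrom = "chrS",
                     start = c(genes$tss[1] + distance,       # first base outside
                               genes$tss[1] + distance - 200L), # last base inside
                     end = c(genes$tss[1] + distance + 300L,
                             genes$tss[1] + distance + 100L))
    }
    # Gene 5 carries both-direction dynamic marks (pattern 5 below). TF01
    # gets binding sites overlapping down by 400 bp and up by 300 bp
    # (conflict, down wins); TF02 overlaps both by 300 bp (tie, up wins).
    conflict <- if (t <= 2) {
      ctr <- genes$tss[5] + 1000L
      if (t == 1) {
        tibble::tibble(chrom = "chrS",
                       start = c(ctr - 1700L, ctr + 1250L),
                       end = c(ctr - 1300L, ctr + 1550L))
      } else {
        tibble::tibble(chrom = "chrS",
                       start = c(ctr - 1500L, ctr + 1250L),
                       end = c(ctr - 1200L, ctr + 1550L))
      }
    }
    sort_peaks(dplyr::bind_rows(c(rows, list(extra), list(conflict))))
  }), tfs)

  # Histone marks: early/late x rep1/rep2. Deterministic pattern per gene
  # index mod 6 covers: stable both stages (0), early-only consistent (1),
  # late-only consistent (2), replicate-inconsistent early (3), cross-stage
  # 1-bp overlap (4), direction conflict for the same mark (5).
  mk_peak <- function(center, half = 300L) {
    tibble::tibble(chrom = "chrS", start = center - half, end = center + half)
  }
  marks <- stats::setNames(lapply(seq_along(mark_names), function(mi) {
    e1 <- list(); e2 <- list(); l1 <- list(); l2 <- list()
    for (g in seq_len(n_genes)) {
      if ((((g - 1) %% length(mark_names)) + 1) != mi && ((g %% 6) != 5)) next
      ctr <- genes$tss[g] + 1000L
      pat <- g %% 6
      if (pat == 0) {                       # present both stages: not dynamic
        e1 <- c(e1, list(mk_peak(ctr))); e2 <- c(e2, list(mk_peak(ctr)))
        l1 <- c(l1, list(mk_peak(ctr))); l2 <- c(l2, list(mk_peak(ctr)))
      } else if (pat == 1) {                # early-exclusive -> "down"
        e1 <- c(e1, list(mk_peak(ctr))); e2 <- c(e2, list(mk_peak(ctr + 100L)))
      } else if (pat == 2) {                # late-exclusive -> "up"
        l1 <- c(l1, list(mk_peak(ctr))); l2 <- c(l2, list(mk_peak(ctr - 100L)))
      } else if (pat == 3) {                # rep-inconsistent early: dropped
        e1 <- c(e1, list(mk_peak(ctr)))
      } else if (pat == 4) {                # 1-bp cross-stage overlap: dropped
        e1 <- c(e1, list(mk_peak(ctr))); e2 <- c(e2, list(mk_peak(ctr)))
        l1 <- c(l1, list(tibble::tibble(chrom = "chrS", start = ctr + 299L,
                                        end = ctr + 800L)))
        l2 <- c(l2, list(tibble::tibble(chrom = "chrS", start = ctr + 299L,
                                        end = ctr + 800L)))
      } else {                              # both directions near one gene
        e1 <- c(e1, list(mk_peak(ctr - 1500L)))
        e2 <- c(e2, list(mk_peak(ctr - 1500L)))
        l1 <- c(l1, list(mk_peak(ctr + 1500L)))
        l2 <- c(l2, list(mk_peak(ctr + 1500L)))
      }
    }
    empty <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())
    list(early = list(rep1 = sort_peaks(dplyr::bind_rows(c(list(empty), e1))),
                      rep2 = sort_peaks(dplyr::bind_rows(c(list(empty), e2)))),
         late = list(rep1 = sort_peaks(dplyr::bind_rows(c(list(empty), l1))),
                     rep2 = sort_peaks(dplyr::bind_rows(c(list(empty), l2)))))
  }), mark_names)

  # ATAC: one profile per stage; early covers odd genes, late covers genes
  # divisible by 3, so both exclusive directions and stable peaks occur.
  atac_early <- sort_peaks(dplyr::bind_rows(lapply(
    seq_len(n_genes)[seq_len(n_genes) %% 2 == 1],
    function(g) mk_peak(genes$tss[g] + 500L, 250L))))
  atac_late <- sort_peaks(dplyr::bind_rows(lapply(
    seq_len(n_genes)[seq_len(n_genes) %% 3 == 0],
    function(g) mk_peak(genes$tss[g] + 500L, 250L))))

  expected <- brute_force_expected(tf_peaks, marks, atac_early, atac_late,
                                   genes, distance)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(file.path(dir, "tf_peaks"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list()
    for (tf in tfs) {
      f <- file.path(dir, "tf_peaks", paste0(tf, ".narrowPeak"))
      write_narrowpeak(tf_peaks[[tf]], f)
      paths[[paste0("tf_", tf)]] <- f
    }
    for (mk in mark_names) {
      for (st in c("early", "late")) for (rp in c("rep1", "rep2")) {
        f <- file.path(dir, sprintf("%s_%s_%s.bed", mk, st, rp))
        write_bed(marks[[mk]][[st]][[rp]], f)
        paths[[sprintf("%s_%s_%s", mk, st, rp)]] <- f
      }
    }
    write_bed(atac_early, file.path(dir, "ATAC_early.bed"))
    write_bed(atac_late, file.path(dir, "ATAC_late.bed"))
    ann <- file.path(dir, "genes.tsv")
    readr::write_tsv(genes, ann)
    paths$atac_early <- file.path(dir, "ATAC_early.bed")
    paths$atac_late <- file.path(dir, "ATAC_late.bed")
    paths$genes <- ann
  }

  list(genes = genes, tf_peaks = tf_peaks, marks = marks,
       atac_early = atac_early, atac_late = atac_late, expected = expected,
       paths = paths, distance = distance)
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle: plain loops over 0-based half-open
# intervals, no interval library. Deliberately naive.

bf_overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
bf_ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

bf_any_overlap <- function(s, e, peaks) {
  if (nrow(peaks) == 0) return(FALSE)
  for (i in seq_len(nrow(peaks))) {
    if (bf_overlaps(s, e, peaks$start[i], peaks$end[i])) return(TRUE)
  }
  FALSE
}

bf_dynamic <- function(rep1, rep2, other1, other2) {
  keep <- logical(nrow(rep1))
  for (i in seq_len(nrow(rep1))) {
    keep[i] <- bf_any_overlap(rep1$start[i], rep1$end[i], rep2) &&
      !bf_any_overlap(rep1$start[i], rep1$end[i], other1) &&
      !bf_any_overlap(rep1$start[i], rep1$end[i], other2)
  }
  rep1[keep, c("chrom", "start", "end")]
}

# bit and overlap metric for one (gene, TF, dyn-set) under window [ws, we)
bf_cell <- function(tfbs, dyn, ws, we) {
  bit <- 0L; metric <- 0
  for (i in seq_len(nrow(tfbs))) {
    ts <- tfbs$start[i]; te <- tfbs$end[i]
    if (!bf_overlaps(ts, te, ws, we)) next
    for (j in seq_len(nrow(dyn))) {
      ol <- bf_ov_len(ts, te, dyn$start[j], dyn$end[j])
      if (ol > 0) {
        bit <- 1L
        ps <- max(ts, dyn$start[j]); pe <- min(te, dyn$end[j])
        metric <- metric + bf_ov_len(ps, pe, ws, we)
      }
    }
  }
  list(bit = bit, metric = metric)
}

brute_force_expected <- function(tf_peaks, marks, atac_early, atac_late,
                                 genes, distance) {
  tfs <- sort(names(tf_peaks))
  mark_names <- names(marks)
  n <- nrow(genes)
  ws <- genes$tss - distance; we <- genes$tss + distance

  dyn <- lapply(marks, function(m) list(
    down = bf_dynamic(m$early$rep1, m$early$rep2, m$late$rep1, m$late$rep2),
    up = bf_dynamic(m$late$rep1, m$late$rep2, m$early$rep1, m$early$rep2)
  ))
  # single-profile accessibility: no replicate requirement
  atac_dyn <- list(
    down = atac_early[vapply(seq_len(nrow(atac_early)), function(i) {
      !bf_any_overlap(atac_early$start[i], atac_early$end[i], atac_late)
    }, logical(1)), c("chrom", "start", "end")],
    up = atac_late[vapply(seq_len(nrow(atac_late)), function(i) {
      !bf_any_overlap(atac_late$start[i], atac_late$end[i], atac_early)
    }, logical(1)), c("chrom", "start", "end")]
  )

  directional <- function(dyn_by_mark) {
    out <- tibble::tibble(gene = genes$gene)
    for (tf in tfs) {
      for (mk in names(dyn_by_mark)) {
        bits_dn <- integer(n); bits_up <- integer(n)
        for (g in seq_len(n)) {
          dn <- bf_cell(tf_peaks[[tf]], dyn_by_mark[[mk]]$down, ws[g], we[g])
          up <- bf_cell(tf_peaks[[tf]], dyn_by_mark[[mk]]$up, ws[g], we[g])
          if (dn$bit == 1L && up$bit == 1L) {
            if (up$metric >= dn$metric) dn$bit <- 0L else up$bit <- 0L
          }
          bits_dn[g] <- dn$bit; bits_up[g] <- up$bit
        }
        out[[evidence_key(tf, mk, "down")]] <- bits_dn
        out[[evidence_key(tf, mk, "up")]] <- bits_up
      }
    }
    out
  }

  diffmark <- directional(dyn)
  diffacc <- directional(list(ATAC = atac_dyn))

  aggr <- tibble::tibble(gene = genes$gene)
  for (tf in tfs) {
    for (dir in c("down", "up")) {
      cols <- evidence_key(tf, mark_names, dir)
      aggr[[evidence_key(tf, "any", dir)]] <-
        as.integer(rowSums(diffmark[cols]) > 0)
    }
  }

  presmark <- tibble::tibble(gene = genes$gene)
  for (tf in tfs) {
    for (mk in mark_names) {
      pool <- dplyr::bind_rows(marks[[mk]]$early$rep1, marks[[mk]]$early$rep2,
                               marks[[mk]]$late$rep1, marks[[mk]]$late$rep2)
      bits <- integer(n)
      for (g in seq_len(n)) {
        bits[g] <- bf_cell(tf_peaks[[tf]], pool, ws[g], we[g])$bit
      }
      presmark[[evidence_key(tf, mk, "present")]] <- bits
    }
  }

  presacc <- tibble::tibble(gene = genes$gene)
  tfbsonly <- tibble::tibble(gene = genes$gene)
  atac_pool <- dplyr::bind_rows(atac_early, atac_late)
  for (tf in tfs) {
    bits_a <- integer(n); bits_t <- integer(n)
    for (g in seq_len(n)) {
      bits_a[g] <- bf_cell(tf_peaks[[tf]], atac_pool, ws[g], we[g])$bit
      hit <- 0L
      for (i in seq_len(nrow(tf_peaks[[tf]]))) {
        if (bf_overlaps(tf_peaks[[tf]]$start[i], tf_peaks[[tf]]$end[i],
                        ws[g], we[g])) hit <- 1L
      }
      bits_t[g] <- hit
    }
    presacc[[evidence_key(tf, "ATAC", "present")]] <- bits_a
    tfbsonly[[evidence_key(tf, "TFBS", "present")]] <- bits_t
  }

  list(DiffMark = diffmark, DiffMarkAggr = aggr, PresMark = presmark,
       DiffAcc = diffacc, PresAcc = presacc, TFBSonly = tfbsonly)
}
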