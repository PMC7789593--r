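# Evidence construction from peak files.
#
# Coordinate convention throughout: 0-based half-open [start, end), the BED
# convention, both on disk and in tibbles. Overlap means >= 1 shared base.
# GRanges objects (1-based closed) are used internally for interval joins.

peaks_gr <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) && any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy start < end (0-based half-open)")
  }
  GenomicRanges::GRanges(
    norm_chrom(peaks$chrom),
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

# Harmonize the "chr" prefix between annotation and peak files.
norm_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

sort_peaks <- function(peaks) {
  dplyr::arrange(peaks, .data$chrom, .data$start, .data$end)
}

has_overlap <- function(a, b) {
  IRanges::overlapsAny(peaks_gr(a), peaks_gr(b))
}

#' Call dynamic (stage-exclusive) mark intervals from replicated peaks
#'
#' A stage-consistent peak is a replicate-1 interval that overlaps (>= 1 bp)
#' any replicate-2 interval of the same stage; it is reported with its
#' replicate-1 coordinates. A consistent early peak with no overlap against
#' either late replicate is a "down" interval (mark lost by the late stage);
#' "up" is the symmetric late-exclusive case.
#'
#' @param early_rep1,early_rep2,late_rep1,late_rep2 Peak tibbles with
#'   `chrom`, `start`, `end` (0-based half-open). If any carries a `mark`
#'   column, all must agree on a single label.
#' @return A list with sorted peak tibbles `up` and `down`.
#' @export
call_dynamic_marks <- function(early_rep1, early_rep2, late_rep1, late_rep2) {
  sets <- list(early_rep1, early_rep2, late_rep1, late_rep2)
  labels <- unique(unlist(lapply(sets, function(s) {
    if ("mark" %in% names(s)) unique(s$mark) else character(0)
  })))
  if (length(labels) > 1) {
    stop("mixed mark labels across replicates: ", paste(labels, collapse = ", "))
  }
  core <- function(x) x[c("chrom", "start", "end")]
  consistent_early <- early_rep1[has_overlap(early_rep1, early_rep2), ]
  consistent_late <- late_rep1[has_overlap(late_rep1, late_rep2), ]
  late_all <- dplyr::bind_rows(core(late_rep1), core(late_rep2))
  early_all <- dplyr::bind_rows(core(early_rep1), core(early_rep2))
  list(
    up = sort_peaks(core(consistent_late)[!has_overlap(consistent_late, early_all), ]),
    down = sort_peaks(core(consistent_early)[!has_overlap(consistent_early, late_all), ])
  )
}

#' Call dynamic accessibility intervals from single-profile stages
#'
#' Single-replicate analogue of [call_dynamic_marks()] for ATAC-seq: "down"
#' intervals are early-stage peaks with no late overlap, "up" the reverse.
#'
#' @param early,late Peak tibbles (`chrom`, `start`, `end`).
#' @return A list with sorted peak tibbles `up` and `down`.
#' @export
call_dynamic_accessibility <- function(early, late) {
  core <- function(x) x[c("chrom", "start", "end")]
  list(
    up = sort_peaks(core(late)[!has_overlap(late, early), ]),
    down = sort_peaks(core(early)[!has_overlap(early, late), ])
  )
}

# Gene windows: [tss - d, tss + d) in 0-based half-open coordinates, centred
# on the TSS; strand is used only upstream, to locate the TSS.
gene_windows_gr <- function(genes, distance) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(genes)), distance > 0)
  if (nrow(genes) == 0) stop("empty gene list")
  if (anyDuplicated(genes$gene)) stop("duplicate gene ids in annotation")
  GenomicRanges::GRanges(
    norm_chrom(genes$chrom),
    IRanges::IRanges(start = pmax(1L, genes$tss - distance + 1L),
                     end = genes$tss + distance)
  )
}

check_chrom_compat <- function(tf_peaks, genes) {
  if (nrow(genes) == 0) stop("empty gene list")
  peak_chroms <- unique(unlist(lapply(tf_peaks, function(p) norm_chrom(p$chrom))))
  if (length(peak_chroms) &&
      !length(intersect(peak_chroms, norm_chrom(genes$chrom)))) {
    stop("no chromosome shared between peaks and gene annotation ",
         "after 'chr' prefix normalization")
  }
}

# One directional evidence column plus its per-gene overlap metric.
# tf_gr: TFBS GRanges; dyn: dynamic-interval tibble (or NULL -> no mark
# filter, every TFBS is flagged); win_gr: gene windows.
# Returns list(bit = 0/1 per gene, metric = overlap bp per gene): bit = 1 iff
# some flagged TFBS overlaps the window; metric = total width of
# TFBS-by-dynamic intersection pieces clipped to the window.
column_bits <- function(tf_gr, dyn, win_gr) {
  n <- length(win_gr)
  if (length(tf_gr) == 0) {
    return(list(bit = integer(n), metric = numeric(n)))
  }
  if (is.null(dyn)) {
    flagged <- tf_gr
    pieces <- tf_gr
  } else {
    dyn_gr <- peaks_gr(dyn)
    ov <- GenomicRanges::findOverlaps(tf_gr, dyn_gr)
    if (length(ov) == 0) return(list(bit = integer(n), metric = numeric(n)))
    flagged <- tf_gr[unique(S4Vectors::queryHits(ov))]
    pieces <- IRanges::pintersect(tf_gr[S4Vectors::queryHits(ov)],
                                  dyn_gr[S4Vectors::subjectHits(ov)])
  }
  bit <- integer(n)
  hit <- GenomicRanges::findOverlaps(flagged, win_gr)
  bit[unique(S4Vectors::subjectHits(hit))] <- 1L
  metric <- numeric(n)
  pv <- GenomicRanges::findOverlaps(pieces, win_gr)
  if (length(pv)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      pieces[S4Vectors::queryHits(pv)], win_gr[S4Vectors::subjectHits(pv)]
    ))
    agg <- rowsum(w, S4Vectors::subjectHits(pv))
    metric[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(bit = bit, metric = metric)
}

#' Build a DiffMark evidence matrix
#'
#' Entry (g, t, m, dir) is 1 iff some binding site of TF t overlaps a dynamic
#' interval of mark m in direction dir AND that binding site overlaps the
#' window `[tss - d, tss + d)` of gene g. When both directions of a mark fire
#' for the same (gene, TF), only the direction with the larger total
#' TFBS-by-dynamic-interval overlap (in bp, clipped to the gene window) is
#' kept; ties keep the late-stage ("up") direction. Set
#' `resolve_conflicts = FALSE` to obtain the raw, pre-resolution bits.
#'
#' @param tf_peaks Named list of peak tibbles, one per TF.
#' @param dyn_marks Named list, one entry per mark, each a list with `up` and
#'   `down` peak tibbles (from [call_dynamic_marks()]).
#' @param genes Gene annotation tibble with `gene`, `chrom`, `strand`, `tss`.
#' @param distance Window half-width d in bp (e.g. 10e3, 50e3, 200e3, 1e6).
#' @param resolve_conflicts Apply the largest-change direction rule.
#' @return A model frame (without `pval`): `gene` plus `8 * n_tfs` binary
#'   columns for 4 marks, keyed `TF=<t>;M=<m>;D=<up|down>`, TFs sorted by
#'   name, directions down before up.
#' @export
build_diffmark <- function(tf_peaks, dyn_marks, genes, distance,
                           resolve_conflicts = TRUE) {
  stopifnot(is.list(tf_peaks), !is.null(names(tf_peaks)),
            is.list(dyn_marks), !is.null(names(dyn_marks)))
  check_chrom_compat(tf_peaks, genes)
  win <- gene_windows_gr(genes, distance)
  tfs <- sort(names(tf_peaks))
  out <- tibble::tibble(gene = genes$gene)
  n_conflicts <- 0L
  for (tf in tfs) {
    if (nrow(tf_peaks[[tf]]) == 0) {
      warning("TF ", tf, " has no peaks; its columns are all zero",
              call. = FALSE)
    }
    tf_gr <- peaks_gr(tf_peaks[[tf]])
    for (mk in names(dyn_marks)) {
      dn <- column_bits(tf_gr, dyn_marks[[mk]]$down, win)
      up <- column_bits(tf_gr, dyn_marks[[mk]]$up, win)
      if (resolve_conflicts) {
        both <- dn$bit == 1L & up$bit == 1L
        n_conflicts <- n_conflicts + sum(both)
        keep_up <- both & up$metric >= dn$metric
        keep_dn <- both & dn$metric > up$metric
        dn$bit[both] <- as.integer(keep_dn[both])
        up$bit[both] <- as.integer(keep_up[both])
      }
      out[[evidence_key(tf, mk, "down")]] <- dn$bit
      out[[evidence_key(tf, mk, "up")]] <- up$bit
    }
  }
  if (n_conflicts > 0) {
    message(n_conflicts,
            " (gene, TF, mark) conflict(s) resolved by largest overlap")
  }
  out
}

#' Aggregate DiffMark evidence across marks, per direction
#'
#' Collapses the per-mark columns of a DiffMark matrix to two columns per TF:
#' the disjunction (bitwise OR) over all marks of that TF's "up" columns, and
#' likewise for "down". Output columns are keyed with mark label `"any"`.
#'
#' @param diffmark_matrix A model frame produced by [build_diffmark()].
#' @return A model frame with `2 * n_tfs` evidence columns.
#' @export
build_diffmarkaggr <- function(diffmark_matrix) {
  keys <- parse_evidence_keys(evidence_columns(diffmark_matrix))
  stopifnot(all(keys$direction %in% c("up", "down")))
  out <- tibble::tibble(gene = diffmark_matrix$gene)
  for (tf in sort(unique(keys$tf))) {
    for (dir in c("down", "up")) {
      cols <- keys$column[keys$tf == tf & keys$direction == dir]
      out[[evidence_key(tf, "any", dir)]] <-
        as.integer(rowSums(diffmark_matrix[cols]) > 0)
    }
  }
  out
}

#' Build a PresMark evidence matrix
#'
#' One column per (TF, mark) with direction `"present"`: the bit is 1 iff a
#' binding site of the TF inside the gene window overlaps any peak of that
#' mark from any stage or replicate.
#'
#' @inheritParams build_diffmark
#' @param mark_peaks Named list, one entry per mark, each a peak tibble or a
#'   list of peak tibbles (stages/replicates are pooled).
#' @return A model frame with `4 * n_tfs` evidence columns (for 4 marks).
#' @export
build_presmark <- function(tf_peaks, mark_peaks, genes, distance) {
  stopifnot(is.list(mark_peaks), !is.null(names(mark_peaks)))
  check_chrom_compat(tf_peaks, genes)
  win <- gene_windows_gr(genes, distance)
  pooled <- lapply(mark_peaks, function(m) {
    if (is.data.frame(m)) m else dplyr::bind_rows(lapply(m, `[`, c("chrom", "start", "end")))
  })
  out <- tibble::tibble(gene = genes$gene)
  for (tf in sort(names(tf_peaks))) {
    tf_gr <- peaks_gr(tf_peaks[[tf]])
    for (mk in names(pooled)) {
      out[[evidence_key(tf, mk, "present")]] <-
        column_bits(tf_gr, pooled[[mk]], win)$bit
    }
  }
  out
}

#' Build DiffAcc / PresAcc evidence matrices from ATAC-seq peaks
#'
#' `build_diffacc()` mirrors [build_diffmark()] with accessibility in place
#' of histone marks: dynamic ATAC intervals are called per stage (single
#' profile per stage, see [call_dynamic_accessibility()]) and each TF gets an
#' accessibility-up and an accessibility-down column, with the same
#' largest-change conflict rule. `build_presacc()` gives one column per TF:
#' an ATAC peak from either stage overlapping a TFBS in the gene window.
#'
#' @inheritParams build_diffmark
#' @param atac_early,atac_late ATAC-seq peak tibbles, one per stage.
#' @return A model frame with `2 * n_tfs` (DiffAcc) or `n_tfs` (PresAcc)
#'   evidence columns, mark label `"ATAC"`.
#' @export
build_diffacc <- function(tf_peaks, atac_early, atac_late, genes, distance,
                          resolve_conflicts = TRUE) {
  dyn <- call_dynamic_accessibility(atac_early, atac_late)
  build_diffmark(tf_peaks, list(ATAC = dyn), genes, distance,
                 resolve_conflicts = resolve_conflicts)
}

#' @rdname build_diffacc
#' @export
build_presacc <- function(tf_peaks, atac_early, atac_late, genes, distance) {
  core <- function(x) x[c("chrom", "start", "end")]
  build_presmark(tf_peaks,
                 list(ATAC = dplyr::bind_rows(core(atac_early), core(atac_late))),
                 genes, distance)
}

#' Build a TFBS-only evidence matrix
#'
#' One column per TF, no epigenomic filter: the bit is 1 iff any binding site
#' of the TF overlaps the gene window.
#'
#' @inheritParams build_diffmark
#' @return A model frame with `n_tfs` evidence columns, keyed
#'   `TF=<t>;M=TFBS;D=present`.
#' @export
build_tfbs_only <- function(tf_peaks, genes, distance) {
  check_chrom_compat(tf_peaks, genes)
  win <- gene_windows_gr(genes, distance)
  out <- tibble::tibble(gene = genes$gene)
  for (tf in sort(names(tf_peaks))) {
    out[[evidence_key(tf, "TFBS", "present")]] <-
      column_bits(peaks_gr(tf_peaks[[tf]]), NULL, win)$bit
  }
  out
}

#' Build an evidence matrix under a named strategy
#'
#' Umbrella dispatcher over the six encoding strategies; the strategy decides
#' which of the epigenomic inputs are consulted.
#'
#' @inheritParams build_diffmark
#' @param strategy One of `"DiffMark"`, `"DiffMarkAggr"`, `"PresMark"`,
#'   `"DiffAcc"`, `"PresAcc"`, `"TFBSonly"`.
#' @param marks Named list per mark of stage/replicate peak tibbles:
#'   `list(early = list(rep1, rep2), late = list(rep1, rep2))`. Needed by the
#'   mark-based strategies.
#' @param atac_early,atac_late ATAC peak tibbles for the accessibility
#'   strategies.
#' @return A model frame (see the individual builders).
#' @export
build_evidence <- function(tf_peaks, genes, strategy, distance, marks = NULL,
                           atac_early = NULL, atac_late = NULL) {
  strategy <- match.arg(strategy, c("DiffMark", "DiffMarkAggr", "PresMark",
                                    "DiffAcc", "PresAcc", "TFBSonly"))
  need_marks <- function() {
    if (is.null(marks)) stop(strategy, " needs `marks`")
    marks
  }
  switch(strategy,
    DiffMark = ,
    DiffMarkAggr = {
      mk <- need_marks()
      dyn <- lapply(mk, function(m) {
        call_dynamic_marks(m$early[[1]], m$early[[2]], m$late[[1]], m$late[[2]])
      })
      dm <- build_diffmark(tf_peaks, dyn, genes, distance)
      if (strategy == "DiffMark") dm else build_diffmarkaggr(dm)
    },
    PresMark = {
      mk <- need_marks()
      pooled <- lapply(mk, function(m) c(m$early, m$late))
      build_presmark(tf_peaks, pooled, genes, distance)
    },
    DiffAcc = {
      if (is.null(atac_early) || is.null(atac_late)) stop("DiffAcc needs ATAC peaks")
      build_diffacc(tf_peaks, atac_early, atac_late, genes, distance)
    },
    PresAcc = {
      if (is.null(atac_early) || is.null(atac_late)) stop("PresAcc needs ATAC peaks")
      build_presacc(tf_peaks, atac_early, atac_late, genes, distance)
    },
    TFBSonly = build_tfbs_only(tf_peaks, genes, distance)
  )
}
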