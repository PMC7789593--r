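# Readers and writers. All genomic coordinates are 0-based half-open on
# disk (BED convention) and in tibbles.

read_interval_file <- function(path, min_cols, what) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0 || all(lines == "")) {
    warning("empty ", what, " file: ", path, call. = FALSE)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected >= %d tab-separated columns, got %d",
                 path, bad[1], min_cols, nf[bad[1]]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop(sprintf("%s line %d: invalid interval (need integer start < end)",
                 path, bad[1]))
  }
  tibble::tibble(chrom = vapply(fields, `[`, "", 1), start = start, end = end,
                 .fields = fields)
}

#' Read a BED3/BED6 peak file
#'
#' @param path File path; `#`, `track` and `browser` lines are skipped.
#' @return A sorted peak tibble with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- read_interval_file(path, 3, "BED")
  if (nrow(raw) == 0) return(raw)
  out <- raw[c("chrom", "start", "end")]
  nf <- lengths(raw$.fields)
  if (all(nf >= 6)) {
    out$name <- vapply(raw$.fields, `[`, "", 4)
    out$score <- suppressWarnings(as.numeric(vapply(raw$.fields, `[`, "", 5)))
    out$strand <- vapply(raw$.fields, `[`, "", 6)
  }
  sort_peaks(out)
}

#' Read a MACS2 narrowPeak file
#'
#' Accepts the 10-column narrowPeak dialect (or plain 6-column BED). Column 9
#' holds -log10(q-value); `qvalue_min` keeps peaks with
#' `qvalue <= qvalue_min`, i.e. `-log10(q) >= -log10(qvalue_min)`.
#'
#' @param path File path.
#' @param qvalue_min Optional q-value threshold (e.g. 0.01).
#' @return A sorted peak tibble with `chrom`, `start`, `end` and, for
#'   10-column input, `name`, `score`, `strand`, `signal`, `pvalue_mlog10`,
#'   `qvalue_mlog10`, `summit`.
#' @export
read_narrowpeak <- function(path, qvalue_min = NULL) {
  raw <- read_interval_file(path, 6, "narrowPeak")
  if (nrow(raw) == 0) return(raw)
  out <- raw[c("chrom", "start", "end")]
  nf <- lengths(raw$.fields)
  full <- all(nf >= 10)
  if (full) {
    out$name <- vapply(raw$.fields, `[`, "", 4)
    out$score <- suppressWarnings(as.numeric(vapply(raw$.fields, `[`, "", 5)))
    out$strand <- vapply(raw$.fields, `[`, "", 6)
    out$signal <- suppressWarnings(as.numeric(vapply(raw$.fields, `[`, "", 7)))
    out$pvalue_mlog10 <- suppressWarnings(as.numeric(vapply(raw$.fields, `[`, "", 8)))
    out$qvalue_mlog10 <- suppressWarnings(as.numeric(vapply(raw$.fields, `[`, "", 9)))
    out$summit <- suppressWarnings(as.integer(vapply(raw$.fields, `[`, "", 10)))
  }
  if (!is.null(qvalue_min)) {
    if (!full) stop("q-value filtering needs 10-column narrowPeak input")
    out <- out[out$qvalue_mlog10 >= -log10(qvalue_min), ]
  }
  sort_peaks(out)
}

#' Write peaks as BED3 / narrowPeak
#'
#' `write_narrowpeak()` emits the 10-column dialect with placeholder
#' name/score/strand and summit at the interval midpoint.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  readr::write_tsv(peaks[c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  out <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(max(n, 0))),
    score = 0L, strand = ".", signal = 1, pvalue_mlog10 = -1,
    qvalue_mlog10 = if ("qvalue_mlog10" %in% names(peaks)) peaks$qvalue_mlog10 else 3,
    summit = as.integer((peaks$end - peaks$start) %/% 2)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `gene`, `log2fc`, `pval` (an optional
#' `qval` is kept when present). Duplicate gene ids are an error.
#'
#' @param path File path.
#' @return A tibble with one row per gene.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("gene", "log2fc", "pval")
  if (!all(need %in% names(tab))) {
    stop("DE table must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(tab), collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene ids in DE table: ",
         paste(utils::head(unique(tab$gene[duplicated(tab$gene)]), 5),
               collapse = ", "))
  }
  tab[c(need, intersect("qval", names(tab)))]
}

#' Read a gene annotation table
#'
#' TSV with header `gene`, `chrom`, `strand`, `tss` and optional gene-body
#' `start` / `end`; all coordinates 0-based.
#'
#' @param path File path.
#' @return A tibble of gene records.
#' @export
read_gene_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("gene", "chrom", "strand", "tss")
  if (!all(need %in% names(tab))) {
    stop("annotation must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) stop("duplicate gene ids in annotation")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (cl in intersect(c("tss", "start", "end"), names(tab))) {
    tab[[cl]] <- as.integer(tab[[cl]])
  }
  tab
}

#' Read and write the evidence-file TSV dialect
#'
#' The dialect is a tab-separated table with header `GENE PVAL <key> ...`
#' where each evidence key encodes TF, mark and direction (see
#' [evidence_key()]), preceded by `#` comment lines recording the tool
#' version and any metadata passed to the writer. Reading then writing with
#' the same metadata is byte-identical.
#'
#' @param path File path.
#' @return `read_evidence()`: a model frame (`gene`, `pval` if present,
#'   evidence columns).
#' @export
read_evidence <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"GENE" %in% names(tab)) stop("evidence file must have a GENE column")
  # base-R strtod is correctly rounded, keeping write/read/write byte-stable
  if ("PVAL" %in% names(tab)) tab$PVAL <- as.numeric(tab$PVAL)
  names(tab)[names(tab) == "GENE"] <- "gene"
  if ("PVAL" %in% names(tab)) names(tab)[names(tab) == "PVAL"] <- "pval"
  for (cl in grep("^TF=", names(tab), value = TRUE)) {
    tab[[cl]] <- as.integer(tab[[cl]])
  }
  check_model_frame(tab, need_pval = "pval" %in% names(tab),
                    need_evidence = FALSE)
  tab
}

#' @rdname read_evidence
#' @param data Model frame to write.
#' @param metadata Optional named list (e.g. seed, config hash) echoed as
#'   `# key: value` comment lines.
#' @export
write_evidence <- function(data, path, metadata = NULL) {
  check_model_frame(data, need_pval = "pval" %in% names(data),
                    need_evidence = FALSE)
  out <- data
  names(out)[names(out) == "gene"] <- "GENE"
  names(out)[names(out) == "pval"] <- "PVAL"
  if ("PVAL" %in% names(out)) {
    # 15 significant digits: decimal -> double -> decimal is the identity at
    # this precision, so write/read/write cycles are byte-stable
    out$PVAL <- sprintf("%.15g", out$PVAL)
  }
  header <- c(
    sprintf("# pgenmi evidence v%s",
            as.character(utils::packageVersion("pgenmi"))),
    if (length(metadata)) sprintf("# %s: %s", names(metadata),
                                  vapply(metadata, as.character, ""))
  )
  readr::write_lines(header, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes the parameter estimates, log-likelihoods, LLR, convergence flag and
#' the training configuration (seed, lambda, restarts).
#'
#' @param fit A `pgenmi_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pgenmi_fit"))
  obj <- list(
    variant = fit$variant,
    params = if (fit$variant == "fw") {
      list(w0 = fit$params$w0, w_tf = as.list(fit$params$w_tf),
           w_mark = as.list(fit$params$w_mark), alpha = fit$params$alpha)
    } else {
      list(w0 = fit$params$w0, w = as.list(fit$params$w),
           alpha = fit$params$alpha)
    },
    loglik = fit$loglik, penalized_obj = fit$penalized_obj, llr = fit$llr,
    null = fit$null, converged = fit$converged,
    config = list(lambda = fit$lambda, seed = fit$seed,
                  restarts = fit$restarts, n_genes = fit$n_genes)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
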