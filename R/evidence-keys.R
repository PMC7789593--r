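#' Compose and parse evidence column keys
#'
#' Evidence columns are named with a compact `TF=<tf>;M=<mark>;D=<direction>`
#' key that encodes the transcription factor, the (histone-mark / accessibility
#' / binding-site) label, and the direction of change. Direction is one of
#' `"up"`, `"down"` or `"present"`; `"present"` is reserved for the
#' presence-based encodings (PresMark, PresAcc, TFBS-only).
#'
#' @param tf Character vector of TF names.
#' @param mark Character vector of mark labels (recycled against `tf`).
#' @param direction `"up"`, `"down"` or `"present"` (recycled).
#'
#' @return `evidence_key()` returns a character vector of keys;
#'   `parse_evidence_keys()` returns a tibble with columns `column`, `tf`,
#'   `mark`, `direction`.
#' @examples
#' evidence_key("JUND", "H3K27ac", "up")
#' parse_evidence_keys(evidence_key(c("JUND", "MAX"), "ATAC", "present"))
#' @export
evidence_key <- function(tf, mark, direction) {
  stopifnot(all(direction %in% c("up", "down", "present")))
  bad <- grepl("[;=\t]", c(tf, mark))
  if (any(bad)) {
    stop("TF and mark labels must not contain ';', '=' or tab characters")
  }
  paste0("TF=", tf, ";M=", mark, ";D=", direction)
}

#' @rdname evidence_key
#' @param keys Character vector of evidence column keys.
#' @export
parse_evidence_keys <- function(keys) {
  m <- stringr::str_match(keys, "^TF=([^;]+);M=([^;]+);D=(up|down|present)$")
  if (anyNA(m[, 1])) {
    stop(
      "malformed evidence column key(s): ",
      paste(utils::head(keys[is.na(m[, 1])], 5), collapse = ", ")
    )
  }
  tibble::tibble(column = keys, tf = m[, 2], mark = m[, 3], direction = m[, 4])
}

#' Identify evidence columns of a model frame
#'
#' A model frame is a tibble with a `gene` column, optionally a `pval` column,
#' and one 0/1 column per evidence type named by [evidence_key()].
#'
#' @param data A model frame.
#' @return Character vector of evidence column names, in frame order.
#' @export
evidence_columns <- function(data) {
  grep("^TF=", names(data), value = TRUE)
}

#' Extract the binary evidence matrix from a model frame
#'
#' @param data A model frame (see [evidence_columns()]).
#' @return Integer matrix, genes in rows (rownames = gene ids), evidence
#'   columns in frame order.
#' @export
as_evidence_matrix <- function(data) {
  check_model_frame(data, need_pval = FALSE, need_evidence = FALSE)
  cols <- evidence_columns(data)
  x <- as.matrix(data[cols])
  storage.mode(x) <- "double"
  rownames(x) <- data$gene
  x
}

# Validate a model frame: unique genes, unique well-formed keys, binary
# entries, pvals in (0, 1] when required.
check_model_frame <- function(data, need_pval = TRUE, need_evidence = TRUE) {
  if (!is.data.frame(data) || !"gene" %in% names(data)) {
    stop("`data` must be a data frame with a `gene` column")
  }
  if (anyDuplicated(data$gene)) {
    stop("duplicate gene ids in `data`: ",
         paste(utils::head(unique(data$gene[duplicated(data$gene)]), 5),
               collapse = ", "))
  }
  cols <- evidence_columns(data)
  if (need_evidence && length(cols) == 0) {
    stop("`data` has no evidence columns (names starting with 'TF=')")
  }
  if (length(cols)) {
    parse_evidence_keys(cols)
    x <- as.matrix(data[cols])
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      stop("evidence entries must all be 0 or 1")
    }
  }
  if (need_pval) {
    if (!"pval" %in% names(data)) stop("`data` must have a `pval` column")
    p <- data$pval
    if (anyNA(p) || any(p <= 0) || any(p > 1)) {
      stop("p-values must lie in (0, 1]; clamp zeros first ",
           "(see transform_de_pvalues(), floor = 1e-12)")
    }
  }
  invisible(data)
}
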