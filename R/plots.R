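#' Plot fitted evidence weights
#'
#' For the full model, a bar chart of per-column weights grouped by TF; for
#' the factorized model, side-by-side bars of the TF and mark-change weights.
#'
#' @param object A `pgenmi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgenmi_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[!td$term %in% c("(w0)", "(alpha)"), ]
  if (object$variant == "fw") {
    td$group <- ifelse(startsWith(td$term, "w_tf:"), "TF weight", "mark-change weight")
    td$label <- sub("^w_(tf|mark):", "", td$term)
    ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$label, .data$estimate),
                                     y = .data$estimate)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::facet_wrap(~group, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "fitted weight")
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$mark, y = .data$estimate,
                                     fill = .data$direction)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~tf) +
      ggplot2::labs(x = "mark", y = "fitted weight") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' Plot a permutation-null LLR distribution
#'
#' Histogram of permuted LLRs with the observed LLR as a dashed line.
#'
#' @param object A `pgm_null` from [shuffled_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgm_null <- function(object, ...) {
  ggplot2::ggplot(object$perm, ggplot2::aes(x = .data$llr)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed_llr, linetype = "dashed") +
    ggplot2::labs(x = "LLR under shuffled evidence", y = "permutations",
                  subtitle = sprintf("observed LLR = %.1f (z = %.1f)",
                                     object$observed_llr, object$z))
}

#' Plot held-out LLR distributions from cross-validation
#'
#' @param object A `pgm_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object (histogram of test LLRs per analysis).
#' @export
autoplot.pgm_cv <- function(object, ...) {
  res <- object$results
  if (any(res$chosen)) res <- res[res$chosen, ]
  ggplot2::ggplot(res, ggplot2::aes(x = .data$test_llr, fill = .data$analysis)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "held-out test LLR", y = "repeats")
}

#' Bar chart of TF contribution scores
#'
#' @param delta_llr_table Tibble from [tf_delta_llr()].
#' @return A ggplot object.
#' @export
plot_tf_contributions <- function(delta_llr_table) {
  stopifnot(all(c("tf", "delta_llr") %in% names(delta_llr_table)))
  ggplot2::ggplot(delta_llr_table,
                  ggplot2::aes(x = stats::reorder(.data$tf, .data$delta_llr),
                               y = .data$delta_llr)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * "LLR"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
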