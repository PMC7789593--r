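#' TF contribution to the model's explanatory power
#'
#' For each TF (or a requested one), zeroes all of that TF's evidence columns
#' for all genes and recomputes the model log-likelihood at the trained
#' weights; the drop `LLR(full) - LLR(zeroed)` is the TF's contribution score.
#' Ranking TFs by this drop reproduces the TF prioritization of the model.
#' By default weights are NOT refit after zeroing (deterministic and cheap);
#' `refit = TRUE` retrains on the ablated matrix instead.
#'
#' @param fit A `pgenmi_fit` (non-null variant).
#' @param data The model frame the fit was trained on (or any frame with the
#'   same evidence columns).
#' @param tfs TF names to score; default all TFs in the fit.
#' @param refit Retrain on the ablated evidence instead of re-evaluating at
#'   the trained weights.
#' @param ... Passed to [pgm_fit()] when `refit = TRUE`.
#' @return A tibble with `tf`, `delta_llr` and `rank`, sorted by decreasing
#'   `delta_llr`; ties are broken by TF name so output is reproducible.
#' @export
tf_delta_llr <- function(fit, data, tfs = NULL, refit = FALSE, ...) {
  stopifnot(inherits(fit, "pgenmi_fit"))
  if (fit$variant == "null") stop("null fits carry no TF evidence to ablate")
  check_model_frame(data)
  known <- sort(unique(fit$keys$tf))
  if (is.null(tfs)) tfs <- known
  bad <- setdiff(tfs, known)
  if (length(bad)) {
    stop("unknown TF(s) ", paste(bad, collapse = ", "),
         "; known TFs: ", paste(known, collapse = ", "))
  }
  X <- as_evidence_matrix(data)[, fit$keys$column, drop = FALSE]
  ll_full <- loglik_at(fit, X, data$pval)
  scores <- purrr::map_dbl(tfs, function(tf) {
    X0 <- X
    X0[, fit$keys$tf == tf] <- 0
    if (refit) {
      ablated <- data
      ablated[fit$keys$column[fit$keys$tf == tf]] <- 0L
      refit_obj <- pgm_fit(ablated, variant = fit$variant,
                           lambda = fit$lambda, ...)
      fit$llr - refit_obj$llr
    } else {
      ll_full - loglik_at(fit, X0, data$pval)
    }
  })
  dplyr::arrange(
    tibble::tibble(tf = tfs, delta_llr = scores),
    dplyr::desc(.data$delta_llr), .data$tf
  ) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Posterior odds that a gene mediates regulatory influence
#'
#' POR_g = Pr(Z_g = 1 | data) / Pr(Z_g = 0 | data)
#'       = pi_g * alpha * p_g^(alpha - 1) / (1 - pi_g),
#' evaluated at the fitted parameters. Finite for p_g = 1 (the enriched
#' density there is alpha).
#'
#' @inheritParams tf_delta_llr
#' @param genes Optional subset of gene ids; default all genes in `data`.
#' @return A tibble with `gene`, `prior` (pi_g) and `por`, in `data` order.
#' @export
posterior_odds <- function(fit, data, genes = NULL) {
  stopifnot(inherits(fit, "pgenmi_fit"))
  check_model_frame(data, need_evidence = fit$variant != "null")
  if (!is.null(genes)) {
    missing <- setdiff(genes, data$gene)
    if (length(missing)) stop("gene(s) not in data: ", paste(missing, collapse = ", "))
    data <- data[match(genes, data$gene), ]
  }
  X <- if (fit$variant == "null") {
    matrix(0, nrow(data), 0)
  } else {
    as_evidence_matrix(data)[, fit$keys$column, drop = FALSE]
  }
  por_at(fit$params, X, data$pval, data$gene)
}

# log-space POR evaluation shared by posterior_odds() and rpor()
por_at <- function(params, X, pvals, genes) {
  ev <- evidence_as_matrix_for(params, X)
  lin <- drop(ev$x %*% ev$w) + params$w0
  lf1 <- log(params$alpha) + (params$alpha - 1) * log(pvals)
  tibble::tibble(
    gene = genes,
    prior = unname(stats::plogis(lin)),
    por = unname(exp(stats::plogis(lin, log.p = TRUE) -
                       stats::plogis(-lin, log.p = TRUE) + lf1))
  )
}

#' Ratio of posterior odds with and without one TF's evidence
#'
#' RPOR(t, g) = POR(g; full evidence) / POR(g; evidence of TF t zeroed for
#' gene g), at the fitted parameters. Genes ranked by RPOR for a TF define
#' that TF's predicted regulon. Computed definitionally as the ratio of two
#' posterior-odds evaluations.
#'
#' @inheritParams tf_delta_llr
#' @param tfs TF names; default all TFs in the fit.
#' @return A long tibble with `tf`, `gene`, `rpor`.
#' @export
rpor <- function(fit, data, tfs = NULL) {
  stopifnot(inherits(fit, "pgenmi_fit"))
  if (fit$variant == "null") stop("null fits carry no TF evidence")
  check_model_frame(data)
  known <- sort(unique(fit$keys$tf))
  if (is.null(tfs)) tfs <- known
  bad <- setdiff(tfs, known)
  if (length(bad)) {
    stop("unknown TF(s) ", paste(bad, collapse = ", "),
         "; known TFs: ", paste(known, collapse = ", "))
  }
  X <- as_evidence_matrix(data)[, fit$keys$column, drop = FALSE]
  full <- por_at(fit$params, X, data$pval, data$gene)
  purrr::map_dfr(tfs, function(tf) {
    X0 <- X
    X0[, fit$keys$tf == tf] <- 0
    ablated <- por_at(fit$params, X0, data$pval, data$gene)
    tibble::tibble(tf = tf, gene = data$gene, rpor = full$por / ablated$por)
  })
}

#' Gene signature from products of RPOR scores
#'
#' Scores each gene by the product of its RPOR values over a set of
#' top-contributing TFs and returns the `n` highest-scoring genes; ties are
#' broken by gene id for reproducible output.
#'
#' @param rpor_table Long tibble from [rpor()] (`tf`, `gene`, `rpor`).
#' @param tfs TFs whose RPORs enter the product; default all TFs present.
#' @param n Signature size (commonly 50, 70 or 100).
#' @return A tibble with `gene`, `score` and `rank`, `n` rows.
#' @export
gene_signature <- function(rpor_table, tfs = NULL, n = 70) {
  stopifnot(all(c("tf", "gene", "rpor") %in% names(rpor_table)), n >= 1)
  if (is.null(tfs)) tfs <- unique(rpor_table$tf)
  missing <- setdiff(tfs, rpor_table$tf)
  if (length(missing)) stop("TF(s) absent from rpor_table: ",
                            paste(missing, collapse = ", "))
  rpor_table |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::summarise(score = prod(.data$rpor), .by = "gene") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::slice_head(n = n) |>
    dplyr::mutate(rank = dplyr::row_number())
}
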