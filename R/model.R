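#' Model parameter containers
#'
#' `pgm_params()` builds the parameter set of the full model: an intercept
#' `w0`, one weight per evidence column, and the beta shape `alpha` of the
#' enriched p-value component. `fw_params()` builds the factorized variant in
#' which the weight of column `(t, m)` is the product `w_tf[t] * w_mark[m]`.
#'
#' The model places each gene's differential-expression p-value in a
#' two-component mixture: Uniform(0,1) when the latent indicator Z_g = 0 and
#' Beta(alpha, 1) (density `alpha * p^(alpha-1)`, enriched near 0 for
#' alpha < 1) when Z_g = 1. The prior Pr(Z_g = 1) is a logistic function of
#' the weighted evidence.
#'
#' @param w0 Intercept of the logistic prior.
#' @param w Named numeric vector of per-column weights; names are evidence
#'   column keys (see [evidence_key()]).
#' @param alpha Beta shape in (0, 1].
#' @return A list of class `pgm_params` / `fw_params`.
#' @examples
#' pgm_params(w0 = -2, w = c("TF=JUND;M=H3K27ac;D=up" = 1.5), alpha = 0.3)
#' @export
pgm_params <- function(w0, w, alpha) {
  stopifnot(is.numeric(w0), length(w0) == 1, is.numeric(w),
            is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  structure(list(w0 = w0, w = w, alpha = alpha), class = "pgm_params")
}

#' @rdname pgm_params
#' @param w_tf Named numeric vector of per-TF weights.
#' @param w_mark Named numeric vector of per-mark-change weights.
#' @export
fw_params <- function(w0, w_tf, w_mark, alpha) {
  stopifnot(is.numeric(w0), length(w0) == 1, is.numeric(w_tf),
            is.numeric(w_mark), is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  if (is.null(names(w_tf)) || is.null(names(w_mark))) {
    stop("`w_tf` and `w_mark` must be named by TF / mark-change label")
  }
  structure(list(w0 = w0, w_tf = w_tf, w_mark = w_mark, alpha = alpha),
            class = "fw_params")
}

# Column weights implied by a parameter set, aligned to `keys`
# (a parsed-key tibble from parse_evidence_keys()).
column_weights <- function(params, keys) {
  if (inherits(params, "fw_params")) {
    miss_t <- setdiff(keys$tf, names(params$w_tf))
    miss_m <- setdiff(paste(keys$mark, keys$direction, sep = "-"),
                      names(params$w_mark))
    # mark-change labels are "<mark>-<direction>" ("ATAC-up", "H3K27ac-down")
    if (length(miss_t) || length(miss_m)) {
      stop("factorized params missing entries for: ",
           paste(c(miss_t, miss_m), collapse = ", "))
    }
    unname(params$w_tf[keys$tf] *
             params$w_mark[paste(keys$mark, keys$direction, sep = "-")])
  } else {
    if (length(params$w) != nrow(keys)) {
      stop(sprintf("weight/evidence dimension mismatch: %d weights for %d columns",
                   length(params$w), nrow(keys)))
    }
    unname(params$w)
  }
}

#' Prior probability of the latent regulation indicator
#'
#' Evaluates Pr(Z_g = 1) = logistic(w0 + sum_k w_k r_gk) for each gene, where
#' r_gk is the binary evidence and w_k the column weight (a free weight per
#' column, or the product w_tf * w_mark for factorized parameters). The
#' computation is numerically stable for logits up to roughly +/-700.
#'
#' @param params A [pgm_params()] or [fw_params()] object.
#' @param evidence A model frame (tibble with evidence columns), a numeric
#'   matrix, or a single numeric evidence row. Column order must match the
#'   weight layout.
#' @return Numeric vector of prior probabilities, one per row.
#' @examples
#' p <- pgm_params(w0 = log(3), w = c("TF=A;M=ATAC;D=present" = 2), alpha = 0.5)
#' prior_probability(p, c(0))  # logistic(log 3) = 0.75
#' @export
prior_probability <- function(params, evidence) {
  ev <- evidence_as_matrix_for(params, evidence)
  stats::plogis(drop(ev$x %*% ev$w) + params$w0)
}

# Normalize `evidence` (frame / matrix / vector) against a parameter layout;
# returns list(x = matrix, w = column weight vector, keys or NULL).
evidence_as_matrix_for <- function(params, evidence) {
  if (is.data.frame(evidence)) {
    cols <- grep("^TF=", names(evidence), value = TRUE)
    x <- as.matrix(evidence[cols])
    if (length(cols) == 0) x <- matrix(0, nrow = nrow(evidence), ncol = 0)
    storage.mode(x) <- "double"
    if ("gene" %in% names(evidence)) rownames(x) <- evidence$gene
    w <- column_weights(params, parse_evidence_keys(cols))
    return(list(x = x, w = w))
  }
  x <- if (is.matrix(evidence)) evidence else matrix(evidence, nrow = 1)
  w <- if (inherits(params, "fw_params")) {
    if (!is.null(colnames(x))) {
      column_weights(params, parse_evidence_keys(colnames(x)))
    } else {
      stop("factorized params need named evidence columns to align weights")
    }
  } else {
    params$w
  }
  if (ncol(x) != length(w)) {
    stop(sprintf("evidence/weight dimension mismatch: expected %d columns, got %d",
                 length(w), ncol(x)))
  }
  list(x = x, w = w)
}

#' Per-gene log marginal density of a p-value
#'
#' Marginalizes the latent indicator analytically:
#' `log[(1 - pi) * 1 + pi * alpha * p^(alpha - 1)]` with
#' `pi = prior_probability(params, evidence)`. Evaluated with a
#' log-sum-exp so that small p-values and small alpha cannot overflow.
#'
#' @inheritParams prior_probability
#' @param pval Numeric vector of p-values in (0, 1], one per evidence row.
#' @return Numeric vector of log densities.
#' @export
gene_log_density <- function(params, pval, evidence) {
  if (any(pval <= 0) || any(pval > 1)) stop("p-values must lie in (0, 1]")
  ev <- evidence_as_matrix_for(params, evidence)
  lin <- drop(ev$x %*% ev$w) + params$w0
  log_mix_density(lin, log(pval), params$alpha)
}

# log[(1-pi) + pi * alpha * exp((alpha-1) * logp)] with pi = plogis(lin),
# entirely in log space.
log_mix_density <- function(lin, logp, alpha) {
  lp1 <- stats::plogis(lin, log.p = TRUE)
  lp0 <- stats::plogis(-lin, log.p = TRUE)
  lf1 <- log(alpha) + (alpha - 1) * logp
  a <- lp0
  b <- lp1 + lf1
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Penalized training objective
#'
#' The objective maximized during training: the log-likelihood of the p-value
#' vector minus an L2 penalty `lambda * sum(w^2)` on the evidence weights
#' only. The intercept `w0` and the beta shape `alpha` are never penalized.
#' For factorized parameters the penalty is
#' `lambda * (sum(w_tf^2) + sum(w_mark^2))`.
#'
#' @inheritParams prior_probability
#' @param data Model frame with `gene`, `pval` and evidence columns.
#' @param lambda Non-negative L2 regularization coefficient.
#' @return Scalar objective value (log-likelihood minus penalty).
#' @export
pgm_objective <- function(params, data, lambda = 0) {
  stopifnot(lambda >= 0)
  is_null_variant <- !inherits(params, "fw_params") && length(params$w) == 0
  check_model_frame(data, need_evidence = !is_null_variant)
  ll <- sum(gene_log_density(params, data$pval,
                             data[evidence_columns(data)]))
  pen <- if (inherits(params, "fw_params")) {
    sum(params$w_tf^2) + sum(params$w_mark^2)
  } else {
    sum(params$w^2)
  }
  ll - lambda * pen
}

# ---------------------------------------------------------------------------
# Internal optimizer machinery. theta layout:
#   pgenmi: c(w0, w[1..K], a_raw)
#   fw:     c(w0, w_tf[1..T], w_mark[free subset], a_raw)
#   null:   c(w0, a_raw)
# alpha = plogis(a_raw) keeps the shape in (0, 1); the mixture is only
# identifiable as an enrichment of small p-values for alpha < 1.

make_layout <- function(keys, variant, fix_w_mark = NULL) {
  if (variant == "null") {
    return(list(variant = "null", n_theta = 2L))
  }
  if (variant == "pgenmi") {
    return(list(variant = "pgenmi", keys = keys, n_w = nrow(keys),
                n_theta = nrow(keys) + 2L))
  }
  tfs <- sort(unique(keys$tf))
  marks <- sort(unique(paste(keys$mark, keys$direction, sep = "-")))
  fixed <- names(fix_w_mark)
  if (!is.null(fixed) && length(setdiff(fixed, marks))) {
    stop("fix_w_mark names not among mark-change labels: ",
         paste(setdiff(fixed, marks), collapse = ", "))
  }
  free_marks <- setdiff(marks, fixed)
  list(variant = "fw", keys = keys, tfs = tfs, marks = marks,
       t_idx = match(keys$tf, tfs),
       m_idx = match(paste(keys$mark, keys$direction, sep = "-"), marks),
       fix_w_mark = fix_w_mark, free_marks = free_marks,
       n_theta = 1L + length(tfs) + length(free_marks) + 1L)
}

unpack_theta <- function(theta, layout) {
  w0 <- theta[1]
  alpha <- stats::plogis(theta[length(theta)])
  if (layout$variant == "null") {
    return(list(w0 = w0, alpha = alpha, wcol = numeric(0)))
  }
  if (layout$variant == "pgenmi") {
    w <- theta[2:(1 + layout$n_w)]
    return(list(w0 = w0, alpha = alpha, w = w, wcol = w))
  }
  nt <- length(layout$tfs)
  w_tf <- theta[2:(1 + nt)]
  w_mark <- stats::setNames(numeric(length(layout$marks)), layout$marks)
  if (length(layout$fix_w_mark)) {
    w_mark[names(layout$fix_w_mark)] <- layout$fix_w_mark
  }
  if (length(layout$free_marks)) {
    w_mark[layout$free_marks] <-
      theta[(1 + nt + 1):(1 + nt + length(layout$free_marks))]
  }
  list(w0 = w0, alpha = alpha, w_tf = stats::setNames(w_tf, layout$tfs),
       w_mark = w_mark, wcol = w_tf[layout$t_idx] * w_mark[layout$m_idx])
}

# Negative penalized objective and its gradient; X is the n x K evidence
# matrix (K = 0 for the null), logp the per-gene log p-value.
neg_objective <- function(theta, X, logp, layout, lambda) {
  pr <- unpack_theta(theta, layout)
  lin <- if (length(pr$wcol)) drop(X %*% pr$wcol) + pr$w0 else rep(pr$w0, length(logp))
  ll <- sum(log_mix_density(lin, logp, pr$alpha))
  pen <- switch(layout$variant,
    null = 0,
    pgenmi = lambda * sum(pr$w^2),
    fw = lambda * (sum(pr$w_tf^2) +
                     sum(pr$w_mark[layout$free_marks]^2))
  )
  -(ll - pen)
}

neg_gradient <- function(theta, X, logp, layout, lambda) {
  pr <- unpack_theta(theta, layout)
  lin <- if (length(pr$wcol)) drop(X %*% pr$wcol) + pr$w0 else rep(pr$w0, length(logp))
  lp1 <- stats::plogis(lin, log.p = TRUE)
  lp0 <- stats::plogis(-lin, log.p = TRUE)
  lf1 <- log(pr$alpha) + (pr$alpha - 1) * logp
  b <- lp1 + lf1
  m <- pmax(lp0, b)
  ll_g <- m + log(exp(lp0 - m) + exp(b - m))
  q1 <- exp(b - ll_g)                    # posterior P(Z_g = 1 | data)
  pi_g <- exp(lp1)
  g_lin <- q1 - pi_g                     # d loglik / d lin_g
  g_w0 <- sum(g_lin)
  a_raw <- theta[length(theta)]
  g_araw <- sum(q1 * (1 / pr$alpha + logp)) * pr$alpha * (1 - stats::plogis(a_raw))
  # note: d alpha / d a_raw = alpha * (1 - alpha); alpha = plogis(a_raw)
  if (layout$variant == "null") {
    return(-c(g_w0, g_araw))
  }
  g_col <- drop(crossprod(X, g_lin))     # d loglik / d wcol_k
  if (layout$variant == "pgenmi") {
    g_w <- g_col - 2 * lambda * pr$w
    return(-c(g_w0, g_w, g_araw))
  }
  wm_col <- pr$w_mark[layout$m_idx]
  wt_col <- pr$w_tf[layout$t_idx]
  g_tf <- vapply(seq_along(layout$tfs), function(t) {
    sum(g_col[layout$t_idx == t] * wm_col[layout$t_idx == t])
  }, numeric(1)) - 2 * lambda * pr$w_tf
  g_mark <- vapply(layout$free_marks, function(mlab) {
    i <- match(mlab, layout$marks)
    sum(g_col[layout$m_idx == i] * wt_col[layout$m_idx == i])
  }, numeric(1)) - 2 * lambda * pr$w_mark[layout$free_marks]
  -c(g_w0, g_tf, g_mark, g_araw)
}
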