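#' Fit a p-value mixture model with evidence-weighted logistic prior
#'
#' Fits pGENMi (one free weight per evidence column), fw-pGENMi (the weight of
#' column `(t, m)` is the product of a per-TF and a per-mark-change weight),
#' or the evidence-free null (intercept and beta shape only) to a model frame,
#' by maximizing the L2-penalized log-likelihood with `stats::optim`
#' (L-BFGS-B, analytic gradients). The beta shape is kept in (0, 1) by a
#' logistic reparameterization; the best of `restarts` starts (first start at
#' zero weights, `w0 = logit(0.1)`, `alpha = 0.5`; subsequent starts jittered)
#' is returned, judged by the penalized objective.
#'
#' For non-null variants a null model is fitted to the same genes and the
#' log-likelihood ratio `llr = loglik - null loglik` (both unpenalized, at the
#' respective optima of penalized training) is recorded.
#'
#' @param data Model frame: tibble with `gene`, `pval` (in (0, 1]) and 0/1
#'   evidence columns named by [evidence_key()].
#' @param variant `"pgenmi"`, `"fw"` or `"null"`.
#' @param lambda Non-negative L2 coefficient on evidence weights (`w0` and
#'   `alpha` are unpenalized; for `"fw"` the penalty is
#'   `sum(w_tf^2) + sum(w_mark^2)` over free entries).
#' @param restarts Number of optimizer starts (>= 1).
#' @param seed Integer seed controlling the jittered restarts.
#' @param max_iters,tol Optimizer controls (`tol` maps to L-BFGS-B `factr` as
#'   `tol / .Machine$double.eps`).
#' @param fix_w_mark Optional named numeric vector pinning some mark-change
#'   weights of the factorized variant (e.g. `c("ATAC-present" = 1)`); fixed
#'   entries are excluded from optimization and from the penalty.
#' @param null_fit Optional pre-computed null `pgenmi_fit` on the same genes,
#'   reused instead of refitting the null.
#'
#' @return An object of class `pgenmi_fit`: a list with `params`
#'   ([pgm_params()] or [fw_params()]), `loglik` (unpenalized), `penalized_obj`,
#'   `llr`, `null` (null-fit summary), `converged`, `variant`, `lambda`,
#'   `seed`, `restarts`, `n_genes`, `keys` (parsed column keys) and `trace`
#'   (per-restart objective values).
#' @seealso [tf_delta_llr()], [posterior_odds()], [rpor()]
#' @examples
#' sim <- simulate_dataset(n_genes = 500, n_tfs = 2,
#'                         mark_changes = "ATAC-present",
#'                         true_w0 = -1, true_w = c(2, 0), true_alpha = 0.3,
#'                         seed = 1)
#' fit <- pgm_fit(sim$data, lambda = 0.1, restarts = 2, seed = 1)
#' glance(fit)
#' @export
pgm_fit <- function(data, variant = c("pgenmi", "fw", "null"), lambda = 0.1,
                    restarts = 5, seed = 1L, max_iters = 500, tol = 1e-9,
                    fix_w_mark = NULL, null_fit = NULL) {
  variant <- match.arg(variant)
  stopifnot(lambda >= 0, restarts >= 1)
  check_model_frame(data, need_evidence = variant != "null")
  cols <- evidence_columns(data)
  if (variant != "null" && length(cols) == 0) {
    stop("non-null variants need at least one evidence column")
  }
  X <- as_evidence_matrix(data)
  logp <- log(data$pval)
  keys <- parse_evidence_keys(cols)
  layout <- make_layout(keys, variant, fix_w_mark)

  inits <- init_matrix(layout, restarts, seed)
  runs <- lapply(seq_len(restarts), function(r) {
    opt <- stats::optim(
      inits[r, ], fn = neg_objective, gr = neg_gradient,
      X = X, logp = logp, layout = layout, lambda = lambda,
      method = "L-BFGS-B",
      control = list(maxit = max_iters, factr = tol / .Machine$double.eps)
    )
    opt
  })
  best <- which.min(vapply(runs, `[[`, numeric(1), "value"))
  opt <- runs[[best]]
  pr <- unpack_theta(opt$par, layout)

  params <- switch(variant,
    null = pgm_params(pr$w0, stats::setNames(numeric(0), character(0)), pr$alpha),
    pgenmi = pgm_params(pr$w0, stats::setNames(pr$w, keys$column), pr$alpha),
    fw = fw_params(pr$w0, pr$w_tf, pr$w_mark, pr$alpha)
  )
  loglik <- -neg_objective(opt$par, X, logp, layout, lambda = 0)

  if (variant == "null") {
    null_info <- list(w0 = pr$w0, alpha = pr$alpha, loglik = loglik)
    llr <- 0
  } else {
    if (is.null(null_fit)) {
      null_fit <- pgm_fit(data[c("gene", "pval")], variant = "null",
                          lambda = 0, restarts = restarts, seed = seed,
                          max_iters = max_iters, tol = tol)
    } else {
      if (!identical(null_fit$variant, "null")) stop("`null_fit` must be a null-variant fit")
      if (null_fit$n_genes != nrow(data)) {
        stop("`null_fit` was fitted to a different number of genes")
      }
    }
    null_info <- list(w0 = null_fit$params$w0, alpha = null_fit$params$alpha,
                      loglik = null_fit$loglik)
    llr <- loglik - null_info$loglik
  }

  structure(list(
    params = params, loglik = loglik, penalized_obj = -opt$value, llr = llr,
    null = null_info, converged = opt$convergence == 0, variant = variant,
    lambda = lambda, seed = seed, restarts = restarts,
    n_genes = nrow(data), keys = keys,
    trace = tibble::tibble(restart = seq_len(restarts),
                           penalized_obj = -vapply(runs, `[[`, numeric(1), "value"),
                           convergence = vapply(runs, `[[`, integer(1), "convergence"))
  ), class = "pgenmi_fit")
}

# Restart initializations: deterministic first row, seeded jitter after.
init_matrix <- function(layout, restarts, seed) {
  n <- layout$n_theta
  base <- numeric(n)
  base[1] <- stats::qlogis(0.1)   # w0: start with a 10% prior
  base[n] <- 0                    # a_raw = 0 -> alpha = 0.5
  inits <- matrix(rep(base, each = restarts), nrow = restarts)
  if (restarts > 1) {
    withr::with_seed(seed, {
      jitter <- matrix(stats::rnorm((restarts - 1) * n, sd = 0.5), ncol = n)
      inits[-1, ] <- inits[-1, , drop = FALSE] + jitter
    })
  }
  inits
}

# Unpenalized log-likelihood of `fit` on an arbitrary evidence matrix /
# p-value pair (used for ΔLLR, held-out evaluation, RPOR).
loglik_at <- function(fit, X, pvals) {
  sum(gene_log_density(fit$params, pvals, X))
}

#' @export
print.pgenmi_fit <- function(x, ...) {
  cat(sprintf("<pgenmi_fit> variant=%s genes=%d columns=%d\n",
              x$variant, x$n_genes, nrow(x$keys)))
  cat(sprintf("  loglik=%.3f llr=%.3f alpha=%.4f w0=%.3f lambda=%g converged=%s\n",
              x$loglik, x$llr, x$params$alpha, x$params$w0, x$lambda,
              x$converged))
  invisible(x)
}

#' Tidy a fitted model into one row per weight
#'
#' @param x A `pgenmi_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and, where applicable, parsed
#'   `tf` / `mark` / `direction` columns. The intercept and beta shape appear
#'   as terms `"(w0)"` and `"(alpha)"`.
#' @export
tidy.pgenmi_fit <- function(x, ...) {
  head_rows <- tibble::tibble(
    term = c("(w0)", "(alpha)"),
    estimate = c(x$params$w0, x$params$alpha),
    tf = NA_character_, mark = NA_character_, direction = NA_character_
  )
  body <- if (x$variant == "pgenmi" && length(x$params$w)) {
    dplyr::mutate(
      parse_evidence_keys(names(x$params$w)),
      term = .data$column, estimate = unname(x$params$w)
    )[, c("term", "estimate", "tf", "mark", "direction")]
  } else if (x$variant == "fw") {
    tibble::tibble(
      term = c(paste0("w_tf:", names(x$params$w_tf)),
               paste0("w_mark:", names(x$params$w_mark))),
      estimate = c(unname(x$params$w_tf), unname(x$params$w_mark)),
      tf = c(names(x$params$w_tf), rep(NA_character_, length(x$params$w_mark))),
      mark = c(rep(NA_character_, length(x$params$w_tf)), names(x$params$w_mark)),
      direction = NA_character_
    )
  } else {
    tibble::tibble(term = character(), estimate = numeric(),
                   tf = character(), mark = character(), direction = character())
  }
  dplyr::bind_rows(head_rows, body)
}

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.pgenmi_fit
#' @return A one-row tibble: `variant`, `n_genes`, `n_columns`, `loglik`,
#'   `llr`, `alpha`, `w0`, `lambda`, `converged`.
#' @export
glance.pgenmi_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, n_genes = x$n_genes, n_columns = nrow(x$keys),
    loglik = x$loglik, llr = x$llr, alpha = x$params$alpha,
    w0 = x$params$w0, lambda = x$lambda, converged = x$converged
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
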