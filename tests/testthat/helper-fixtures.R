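# Shared test helpers: hand-built parameter sets, a fake fit wrapper so score
# functions can be exercised at chosen parameters, and a naive linear-space
# density oracle.

# Wrap a parameter set as a pgenmi_fit so posterior_odds()/rpor()/
# tf_delta_llr() can be evaluated at hand-chosen parameters.
fake_fit <- function(params, null_loglik = 0) {
  keys <- if (inherits(params, "fw_params")) {
    stop("fake_fit only supports pgm_params in tests")
  } else if (length(params$w)) {
    parse_evidence_keys(names(params$w))
  } else {
    parse_evidence_keys(character(0))
  }
  structure(list(
    params = params, keys = keys,
    variant = if (length(params$w)) "pgenmi" else "null",
    loglik = NA_real_, llr = NA_real_, lambda = 0,
    null = list(w0 = params$w0, alpha = params$alpha, loglik = null_loglik)
  ), class = "pgenmi_fit")
}

# Naive two-term marginalization in linear space; the oracle for
# gene_log_density().
naive_log_density <- function(w0, w, alpha, pval, x) {
  pi_g <- 1 / (1 + exp(-(w0 + sum(w * x))))
  log((1 - pi_g) * 1 + pi_g * alpha * pval^(alpha - 1))
}

# Small informative simulated dataset reused across tests (one strong column
# among 6); built once per test run.
informative_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(
        n_genes = 4000, n_tfs = 3,
        mark_changes = c("H3K27ac-down", "H3K27ac-up"),
        true_w0 = -2, true_w = c(3, 0, 0, 0, 0, 0), true_alpha = 0.2,
        evidence_density = 0.1, seed = 42
      )
    }
    cache
  }
})
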