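# small in-code fixtures shared across test files

tiny_prior <- function(block_ids, p = 1, q = 99) {
  timmrd:::validate_background_prior(
    data.frame(block_id = block_ids, p = p, q = q,
               n_samples_used = 10L, fit_method = "moments",
               stringsAsFactors = FALSE))
}

tiny_panel <- function(block_ids, beta_t = 0.8, beta_n = 0.02, patient_id = "pt1") {
  patient_panel(patient_id, block_ids, rep_len(beta_t, length(block_ids)),
                rep_len(beta_n, length(block_ids)))
}

tiny_counts <- function(block_ids, n_total, n_meth, sample_id = "s1") {
  block_counts(sample_id, block_ids, n_total, n_meth)
}

# closed-form beta-binomial log-pmf: the analytic oracle for the quadrature
betabinom_lpmf <- function(N, M, p, q) {
  lchoose(N, M) + lbeta(M + p, N - M + q) - lbeta(p, q)
}

# direct numerical-integration oracle for the mixture marginal, independent
# of the package's quadrature path
integrate_marginal <- function(alpha, gamma, N, M, beta_t, beta_n, p, q) {
  f <- function(b0) {
    stats::dbinom(M, N, alpha * beta_t + gamma * beta_n + (1 - alpha - gamma) * b0) *
      stats::dbeta(b0, p, q)
  }
  log(stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value)
}

# build a timeline directly from bare vectors (no fitting involved)
mk_timeline <- function(patient_id, days, labels, calls, scores = NULL, max_af = 0,
                        relapsed = FALSE, relapse_day = NA_integer_, dfs_days = NULL) {
  n <- length(days)
  samples <- data.frame(
    sample_id = sprintf("%s_s%d", patient_id, seq_len(n)),
    timepoint_label = rep_len(labels, n),
    day_from_surgery = as.integer(days),
    max_af = rep_len(max_af, n),
    stringsAsFactors = FALSE)
  scores <- if (is.null(scores)) ifelse(rep_len(calls, n) == "high", 10, 1) else rep_len(scores, n)
  fits <- lapply(seq_len(n), function(i) {
    list(alpha_hat = 0.01, gamma_hat = 0, score = scores[i], call = rep_len(calls, n)[i])
  })
  names(fits) <- samples$sample_id
  build_timeline(samples, fits,
                 list(patient_id = patient_id, relapsed = relapsed,
                      relapse_day = relapse_day,
                      dfs_days = dfs_days %||% (if (relapsed) relapse_day else max(days))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
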