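test_that("the mixture mean is the stated convex combination", {
  expect_equal(mixture_mean(0, 0, 0.8, 0.3, 0.01), 0.01)
  expect_equal(mixture_mean(1 - 1e-9, 0, 0.8, 0.3, 0.01), 0.8, tolerance = 1e-7)
  expect_equal(mixture_mean(0.5, 0.25, 0.8, 0.4, 0), 0.5)
  expect_error(mixture_mean(0.6, 0.4, 0.5, 0.5, 0.5), "constraint")
  expect_error(mixture_mean(-0.1, 0, 0.5, 0.5, 0.5), "non-negative")
})

test_that("the block marginal reduces to the analytic beta-binomial at alpha = gamma = 0", {
  # uniform prior: marginal is discrete-uniform on 0..N
  expect_equal(block_marginal_loglik(0, 0, 10L, 3L, 0.8, 0.1, 1, 1), log(1 / 11),
               tolerance = 1e-12)
  for (p in c(0.5, 1, 2, 8)) {
    for (q in c(0.5, 2, 8)) {
      for (N in c(1L, 7L, 30L)) {
        for (M in unique(c(0L, 1L, N %/% 2L, N))) {
          expect_equal(block_marginal_loglik(0, 0, N, M, 0.8, 0.1, p, q),
                       betabinom_lpmf(N, M, p, q), tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("uncovered blocks carry no information and bad inputs are rejected", {
  expect_identical(block_marginal_loglik(0.3, 0.1, 0L, 0L, 0.8, 0.1, 2, 8), 0)
  expect_error(block_marginal_loglik(0, 0, 5L, 6L, 0.8, 0.1, 2, 8), "M <= N")
  expect_error(block_marginal_loglik(0, 0, 5L, 2L, 0.8, 0.1, -1, 8), "positive")
  expect_error(block_marginal_loglik(0.7, 0.4, 5L, 2L, 0.8, 0.1, 2, 8), "constraint")
})

test_that("the block marginal is a normalized pmf for nonzero mixture fractions", {
  for (par in list(c(0, 0), c(0.1, 0), c(0.05, 0.3), c(0.4, 0.4))) {
    for (pq in list(c(0.5, 0.5), c(1, 9), c(2, 8))) {
      for (N in c(5L, 30L)) {
        total <- sum(vapply(0:N, function(M) {
          exp(block_marginal_loglik(par[1], par[2], N, M, 0.85, 0.25, pq[1], pq[2]))
        }, 0))
        expect_equal(total, 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("the total log-likelihood sums block marginals and matches an integration oracle", {
  prior <- tiny_prior(c("b1", "b2", "b3"), p = c(1, 1.5, 0.8), q = c(99, 60, 120))
  panel <- patient_panel("pt", c("b1", "b2", "b3"), c(0.8, 0.7, 0.9), c(0.05, 0.1, 0))
  cnt <- tiny_counts(c("b1", "b2"), c(200L, 150L), c(6L, 3L))

  # single-block panel equals the block marginal
  p1 <- patient_panel("pt", "b1", 0.8, 0.05)
  expect_equal(total_loglik(0.02, 0.1, p1, cnt, prior),
               block_marginal_loglik(0.02, 0.1, 200L, 6L, 0.8, 0.05, 1, 99))

  # permutation invariance (b3 has no counts: contributes zero)
  perm <- patient_panel("pt", c("b3", "b1", "b2"), c(0.9, 0.8, 0.7), c(0, 0.05, 0.1))
  expect_equal(total_loglik(0.01, 0.1, panel, cnt, prior),
               total_loglik(0.01, 0.1, perm, cnt, prior))

  # independent adaptive-integration oracle
  oracle <- integrate_marginal(0.01, 0.1, 200L, 6L, 0.8, 0.05, 1, 99) +
    integrate_marginal(0.01, 0.1, 150L, 3L, 0.7, 0.1, 1.5, 60)
  expect_equal(total_loglik(0.01, 0.1, panel, cnt, prior), oracle, tolerance = 1e-6)

  expect_error(total_loglik(0.01, 0.1, panel,
                            tiny_counts("b9", 10L, 1L), tiny_prior("b9")),
               "missing from the background prior")
})

test_that("deep-coverage blocks exceeding the base quadrature order stay exact", {
  # N far above 2 * quad_order - 1 forces the per-block order escalation
  for (N in c(400L, 900L)) {
    M <- as.integer(round(N * 0.012))
    expect_equal(block_marginal_loglik(0, 0, N, M, 0.8, 0.1, 0.7, 80),
                 betabinom_lpmf(N, M, 0.7, 80), tolerance = 1e-8)
    expect_equal(block_marginal_loglik(0.02, 0, N, M, 0.8, 0.1, 0.7, 80),
                 integrate_marginal(0.02, 0, N, M, 0.8, 0.1, 0.7, 80), tolerance = 1e-7)
  }
})

test_that("the classification threshold is the chi-square(1) quantile", {
  expect_equal(round(classification_threshold(0.98), 3), 5.412)
  expect_equal(classification_threshold(0.5), qchisq(0.5, 1))
  expect_equal(round(classification_threshold(0.5), 3), 0.455)
  expect_lt(classification_threshold(1e-8), 1e-6)
  expect_error(classification_threshold(0), "between 0 and 1")
  expect_error(classification_threshold(1), "between 0 and 1")
})

test_that("classification is strict at the threshold", {
  thr <- classification_threshold(0.98)
  expect_equal(classify(7.978, thr), "high")
  expect_equal(classify(4.244, thr), "low")
  expect_equal(classify(5.412, 5.412), "low")
  expect_equal(classify(5.4121, 5.412), "high")
  expect_error(classify(-1, thr), "non-negative")
})

test_that("boundary estimates score zero and the Wald score matches the LRT asymptotically", {
  ll <- function(a, g) -(a - 0.02)^2 * 5000 - g^2 * 100
  expect_equal(wald_score(ll, 0, 0)$score, 0)
  ws <- wald_score(ll, 0.02, 0)
  # exact quadratic surface: information 10000, score = 0.02^2 * 10000 = 4
  expect_equal(ws$score, 4, tolerance = 1e-4)
  expect_equal(ws$alpha_se, 0.01, tolerance = 1e-4)

  # on simulated samples the Wald score tracks 2 * (loglik_full - loglik_null)
  spec <- simulation_spec(n_blocks = 500L, n_dmb_true = 500L, seed = 31L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  panel <- select_patient_dmbs(tis$tumor, tis$normal, prior)
  rel <- vapply(1:5, function(k) {
    cnt <- simulate_plasma_mixture(0.05, 0, tis$tumor, tis$normal, prior, spec,
                                   seed = 600 + k)
    fit <- fit_timmrd(panel, cnt, prior)
    abs(fit$score / (2 * (fit$loglik_full - fit$loglik_null)) - 1)
  }, 0)
  expect_lt(median(rel), 0.05)
})

test_that("the constrained MLE recovers simulated tumor fractions", {
  spec <- simulation_spec(n_blocks = 300L, n_dmb_true = 300L, seed = 41L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  panel <- select_patient_dmbs(tis$tumor, tis$normal, prior)
  for (k in 1:3) {
    cnt <- simulate_plasma_mixture(0.05, 0, tis$tumor, tis$normal, prior, spec,
                                   seed = 700 + k)
    fit <- fit_timmrd(panel, cnt, prior)
    expect_lt(abs(fit$alpha_hat - 0.05), 0.01)
    expect_equal(fit$call, "high")
    expect_true(fit$converged)
    # constraint safety and internal consistency
    expect_gte(fit$alpha_hat, 0)
    expect_gte(fit$gamma_hat, 0)
    expect_lt(fit$alpha_hat + fit$gamma_hat, 1)
    expect_gte(fit$loglik_full, fit$loglik_null)
    expect_gte(fit$score, 0)
  }
  # background-only sample: near-zero estimate, low call
  cnt0 <- simulate_plasma_mixture(0, 0, tis$tumor, tis$normal, prior, spec, seed = 800)
  fit0 <- fit_timmrd(panel, cnt0, prior)
  expect_lt(fit0$alpha_hat, 5e-3)
  expect_equal(fit0$call, "low")
})

test_that("mean timMRD-scores increase with the simulated tumor fraction", {
  spec <- simulation_spec(n_blocks = 200L, n_dmb_true = 200L, seed = 51L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  panel <- select_patient_dmbs(tis$tumor, tis$normal, prior)
  fracs <- c(0, 1e-4, 1e-3, 1e-2, 1e-1)
  dil <- simulate_dilution_series(fracs, reps = 8L, spec)
  mean_score <- vapply(fracs, function(f) {
    ids <- dil$labels$sample_id[dil$labels$true_fraction == f]
    mean(vapply(ids, function(id) fit_timmrd(panel, dil$samples[[id]], prior)$score, 0))
  }, 0)
  expect_true(all(diff(mean_score) >= 0))
})

test_that("the optimizer matches the exhaustive grid oracle on small panels", {
  spec <- simulation_spec(n_blocks = 25L, n_dmb_true = 25L, seed = 61L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  panel <- select_patient_dmbs(tis$tumor, tis$normal, prior)
  for (k in 1:3) {
    a_true <- c(0.03, 0.1, 0)[k]
    cnt <- simulate_plasma_mixture(a_true, 0.05, tis$tumor, tis$normal, prior, spec,
                                   seed = 900 + k)
    fit <- fit_timmrd(panel, cnt, prior)
    g <- grid_oracle_fit(panel, cnt, prior, grid_step = 0.005,
                         alpha_max = 0.4, gamma_max = 0.6)
    expect_lte(abs(fit$alpha_hat - g$alpha_hat), 0.005)
    expect_lte(g$loglik_full, fit$loglik_full + 1e-6)
  }
})

test_that("a non-identifiable flat likelihood yields a flat grid surface", {
  # tumor, normal and background indistinguishable at very high concentration
  prior <- tiny_prior(c("b1", "b2"), p = 5e5, q = 5e5)  # mean 0.5, tiny variance
  panel <- patient_panel("pt", c("b1", "b2"), c(0.5, 0.5), c(0.5, 0.5))
  cnt <- tiny_counts(c("b1", "b2"), c(40L, 60L), c(20L, 30L))
  ctx <- timmrd:::build_score_context(panel, cnt, prior)
  vals <- vapply(seq(0, 0.9, by = 0.1), function(a) timmrd:::ctx_loglik(ctx, a, 0.05), 0)
  expect_lt(max(vals) - min(vals), 1e-4)
})

test_that("score tables are written with the expected schema", {
  fits <- list(sA = structure(list(alpha_hat = 0.01, gamma_hat = 0, score = 6.1,
                                   call = "high", n_blocks_used = 10L, converged = TRUE),
                              class = "timmrd_fit"))
  f <- withr::local_tempfile()
  manifest <- data.frame(sample_id = "sA", patient_id = "p1", timepoint_label = "B")
  write_score_table(fits, f, manifest)
  tab <- read.delim(f)
  expect_equal(names(tab), c("sample_id", "patient_id", "timepoint_label", "alpha_hat",
                             "gamma_hat", "score", "call", "n_blocks_used", "converged"))
  expect_equal(tab$call, "high")
  expect_equal(tab$patient_id, "p1")
})
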