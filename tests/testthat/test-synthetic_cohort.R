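test_that("tissue pairs plant exactly the requested DMBs, deterministically", {
  spec <- simulation_spec(n_blocks = 1000L, n_dmb_true = 50L, seed = 1L)
  tis <- simulate_tissue_pair(spec)
  expect_length(tis$truth, 50L)
  expect_true(all(tis$truth %in% tis$tumor$block_id))
  tis2 <- simulate_tissue_pair(spec)
  expect_identical(tis, tis2)
  # planted blocks are strongly hypermethylated relative to matched normal
  i <- match(tis$truth, tis$tumor$block_id)
  expect_true(all(tis$tumor$level[i] - tis$normal$level[i] > 0.4))
})

test_that("a null tissue pair has tumor approximately equal to normal", {
  spec <- simulation_spec(n_blocks = 500L, n_dmb_true = 0L, seed = 2L)
  tis <- simulate_tissue_pair(spec)
  expect_length(tis$truth, 0L)
  expect_lt(max(abs(tis$tumor$level - tis$normal$level)), 5 * spec$tumor_noise_sd)
})

test_that("healthy plasma matches its generating beta moments and depth model", {
  spec <- simulation_spec(n_blocks = 40L, n_dmb_true = 0L, seed = 3L)
  healthy <- simulate_healthy_plasma(spec, 200L)
  expect_length(healthy$samples, 200L)
  ratio <- sapply(healthy$samples, function(s) ifelse(s$n_total > 0, s$n_meth / s$n_total, NA))
  depth <- sapply(healthy$samples, function(s) s$n_total)
  truth <- true_background_prior(spec)
  pm <- truth$p / (truth$p + truth$q)
  # per-block mean ratio within 3 standard errors of the prior mean
  vr <- pm * (1 - pm) * (1 + (spec$depth_mean - 1) / (truth$p + truth$q + 1)) / spec$depth_mean
  se <- sqrt(vr / rowSums(!is.na(ratio)))
  dev <- abs(rowMeans(ratio, na.rm = TRUE) - pm) / se
  expect_lt(mean(dev > 3), 0.05)
  expect_lt(abs(mean(depth) - spec$depth_mean) / spec$depth_mean, 0.05)
  expect_length(simulate_healthy_plasma(spec, 1L)$samples, 1L)
})

test_that("plasma mixtures honour the generative model and reduce to healthy plasma", {
  spec <- simulation_spec(n_blocks = 60L, n_dmb_true = 10L, seed = 4L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  healthy <- simulate_healthy_plasma(spec, 3L)
  mix0 <- simulate_plasma_mixture(0, 0, tis$tumor, tis$normal, prior, spec,
                                  seed = timmrd:::seed_plus(spec$seed, 1000 + 2))
  expect_equal(mix0$n_total, healthy$samples[[2]]$n_total)
  expect_equal(mix0$n_meth, healthy$samples[[2]]$n_meth)
  expect_error(simulate_plasma_mixture(0.6, 0.5, tis$tumor, tis$normal, prior, spec),
               "constraint")
  # near-pure tumor at deep coverage concentrates on the tumor profile
  spec_deep <- simulation_spec(n_blocks = 60L, n_dmb_true = 10L, depth_mean = 10000,
                               depth_dispersion = 1e6, seed = 4L)
  mix1 <- simulate_plasma_mixture(0.99, 0, tis$tumor, tis$normal, prior, spec_deep, seed = 9L)
  i <- match(tis$truth, mix1$block_id)
  expect_lt(max(abs(mix1$n_meth[i] / mix1$n_total[i] - tis$tumor$level[i])), 0.05)
})

test_that("planted-block mixture ratios match the expected mixture mean", {
  # fixed shapes: background mean exactly 0.01; tumor level exactly 0.8
  spec <- simulation_spec(n_blocks = 50L, n_dmb_true = 50L, p_range = c(1, 1),
                          q_range = c(99, 99), tumor_range = c(0.8, 0.8),
                          depth_mean = 10000, depth_dispersion = 1e6, seed = 5L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  ratios <- vapply(1:30, function(k) {
    m <- simulate_plasma_mixture(0.01, 0, tis$tumor, tis$normal, prior, spec, seed = 100 + k)
    mean(m$n_meth / m$n_total)
  }, 0)
  expect_lt(abs(mean(ratios) - (0.99 * 0.01 + 0.01 * 0.8)), 3e-4)
})

test_that("dilution series are labelled, sized and seeded reproducibly", {
  spec <- simulation_spec(n_blocks = 30L, n_dmb_true = 10L, seed = 6L)
  dil <- simulate_dilution_series(c(0.1, 0), reps = 5L, spec)
  expect_length(dil$samples, 10L)
  expect_equal(nrow(dil$labels), 10L)
  expect_setequal(unique(dil$labels$true_fraction), c(0.1, 0))
  dil2 <- simulate_dilution_series(c(0.1, 0), reps = 5L, spec)
  expect_identical(dil$samples, dil2$samples)
  # replicate r shares background draws across fractions (common random numbers)
  s1 <- dil$samples[[dil$labels$sample_id[dil$labels$true_fraction == 0.1][1]]]
  s0 <- dil$samples[[dil$labels$sample_id[dil$labels$true_fraction == 0][1]]]
  expect_equal(s1$n_total, s0$n_total)
  expect_true(all(s1$n_meth >= s0$n_meth - 1L))  # near-monotone coupling
})

test_that("all generated counts satisfy 0 <= M <= N", {
  spec <- simulation_spec(n_blocks = 100L, n_dmb_true = 20L, seed = 7L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  for (a in c(0, 0.3, 0.9)) {
    cnt <- simulate_plasma_mixture(a, 0.05, tis$tumor, tis$normal, prior, spec, seed = 50 + a * 10)
    expect_true(all(cnt$n_meth >= 0 & cnt$n_meth <= cnt$n_total))
  }
})

test_that("longitudinal cohorts are deterministic with coherent clinical annotation", {
  spec <- simulation_spec(n_blocks = 50L, n_dmb_true = 20L, seed = 8L)
  lspec <- longitudinal_spec(n_patients = 12L, relapse_fraction = 0.5, seed = 8L)
  co <- simulate_longitudinal_cohort(lspec, spec)
  expect_length(co$patients, 12L)
  co2 <- simulate_longitudinal_cohort(lspec, spec)
  expect_identical(co$patients, co2$patients)
  for (pt in co$patients) {
    expect_true(all(diff(pt$manifest$day_from_surgery) > 0))
    if (pt$relapsed) {
      expect_false(is.na(pt$relapse_day))
      expect_true(all(pt$manifest$day_from_surgery <= pt$relapse_day))
      expect_equal(pt$dfs_days, pt$relapse_day)
    } else {
      expect_true(is.na(pt$relapse_day))
      # cured: no postoperative ctDNA
      post <- pt$manifest$day_from_surgery >= 0
      expect_true(all(pt$manifest$true_alpha[post] == 0))
      expect_true(all(pt$manifest$max_af[post] == 0))
    }
    expect_true(all(pt$manifest$true_alpha[pt$manifest$day_from_surgery < 0] > 0))
  }
})

test_that("a zero-relapse cohort is entirely relapse-free", {
  spec <- simulation_spec(n_blocks = 30L, n_dmb_true = 10L, seed = 9L)
  co <- simulate_longitudinal_cohort(longitudinal_spec(n_patients = 8L, relapse_fraction = 0,
                                                       seed = 9L), spec)
  expect_true(all(!vapply(co$patients, `[[`, TRUE, "relapsed")))
  post_alpha <- unlist(lapply(co$patients, function(p) {
    p$manifest$true_alpha[p$manifest$day_from_surgery >= 0]
  }))
  expect_true(all(post_alpha == 0))
})

test_that("simulated data are most likely under their own generating parameters", {
  spec <- simulation_spec(n_blocks = 100L, n_dmb_true = 100L, seed = 10L)
  tis <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  panel <- select_patient_dmbs(tis$tumor, tis$normal, prior)
  a_true <- 0.08
  diffs <- vapply(1:20, function(k) {
    cnt <- simulate_plasma_mixture(a_true, 0, tis$tumor, tis$normal, prior, spec, seed = 300 + k)
    total_loglik(a_true, 0, panel, cnt, prior) -
      total_loglik(a_true + 0.05, 0, panel, cnt, prior)
  }, 0)
  expect_gt(mean(diffs), 0)
  diffs2 <- vapply(1:20, function(k) {
    cnt <- simulate_plasma_mixture(a_true, 0, tis$tumor, tis$normal, prior, spec, seed = 300 + k)
    total_loglik(a_true, 0, panel, cnt, prior) -
      total_loglik(max(a_true - 0.05, 0), 0, panel, cnt, prior)
  }, 0)
  expect_gt(mean(diffs2), 0)
})
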