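# Seeded generators producing every input the pipeline consumes, with the
# statistical structure the scoring model assumes: per-block beta-distributed
# background methylation, planted tumor-hypermethylated DMBs, overdispersed
# per-block depths, binomial read sampling, plasma mixtures at specified
# (alpha, gamma), and longitudinal cohorts with relapse-driven re-emergence.

seed_plus <- function(seed, k) (as.numeric(seed) + k) %% 2147483647

#' Panel-level simulation specification
#'
#' Defines the synthetic methylation panel: number of blocks, how many carry
#' planted tumor hypermethylation, the ranges of the per-block background
#' beta shapes, tumor methylation levels, and the sequencing depth model.
#' Depths are negative-binomial (mean `depth_mean`, size `depth_dispersion`)
#' to mimic the variable cfDNA input of real libraries.
#'
#' @param n_blocks number of panel blocks.
#' @param n_dmb_true number of planted tumor-hypermethylated blocks
#'   (`<= n_blocks`).
#' @param p_range,q_range uniform ranges for the background beta shapes
#'   `(p_j, q_j)`; the defaults give low background methylation (mean about
#'   0.005-0.03) with concentration comfortably above the panel-selection
#'   floor.
#' @param tumor_range uniform range of tumor methylation levels on planted
#'   blocks.
#' @param tumor_noise_sd Gaussian sd of tumor-minus-normal noise on
#'   non-planted blocks.
#' @param normal_noise_sd Gaussian sd of the adjacent-normal level around
#'   the background prior mean.
#' @param depth_mean,depth_dispersion negative-binomial depth model per
#'   block (mean and size).
#' @param tissue_depth supporting depth recorded for tissue profiles.
#' @param seed integer master seed; every generated object is a
#'   deterministic function of the spec.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_blocks = 1000L, n_dmb_true = 50L,
                            p_range = c(0.4, 2), q_range = c(40, 150),
                            tumor_range = c(0.6, 0.9), tumor_noise_sd = 0.02,
                            normal_noise_sd = 0.01,
                            depth_mean = 200, depth_dispersion = 10,
                            tissue_depth = 500L, seed = 1L) {
  if (n_dmb_true > n_blocks) stop_timmrd("n_dmb_true must not exceed n_blocks")
  if (depth_mean < 0) stop_timmrd("depth_mean must be non-negative")
  structure(list(n_blocks = as.integer(n_blocks), n_dmb_true = as.integer(n_dmb_true),
                 p_range = p_range, q_range = q_range, tumor_range = tumor_range,
                 tumor_noise_sd = tumor_noise_sd, normal_noise_sd = normal_noise_sd,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 tissue_depth = as.integer(tissue_depth), seed = as.integer(seed)),
            class = "simulation_spec")
}

# per-block true background shapes; a deterministic function of the spec
sim_block_params <- function(spec) {
  with_seed(spec$seed, {
    data.frame(block_id = sprintf("blk%05d", seq_len(spec$n_blocks)),
               p = stats::runif(spec$n_blocks, spec$p_range[1], spec$p_range[2]),
               q = stats::runif(spec$n_blocks, spec$q_range[1], spec$q_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Block definitions for a simulated panel
#'
#' @param spec a [simulation_spec()].
#' @return A `block_defs` data frame with synthetic coordinates.
#' @export
simulate_block_defs <- function(spec) {
  n <- spec$n_blocks
  block_defs(sprintf("blk%05d", seq_len(n)), "chr1",
             (seq_len(n) - 1L) * 1000L, (seq_len(n) - 1L) * 1000L + 200L,
             rep(10L, n))
}

#' True background prior of a simulated panel
#'
#' The per-block Beta(p, q) shapes the generator draws from, packaged as a
#' `background_prior` with `fit_method = "known"`. Useful for separating
#' prior-estimation error from scoring error in experiments.
#'
#' @param spec a [simulation_spec()].
#' @return A `background_prior` data frame.
#' @export
true_background_prior <- function(spec) {
  bp <- sim_block_params(spec)
  validate_background_prior(data.frame(block_id = bp$block_id, p = bp$p, q = bp$q,
                                       n_samples_used = 0L, fit_method = "known",
                                       stringsAsFactors = FALSE))
}

#' Simulate a matched tumor / adjacent-normal tissue pair
#'
#' Adjacent-normal levels sit near the background prior mean with small
#' Gaussian noise; a seeded subset of `n_dmb_true` blocks gets tumor levels
#' drawn from `tumor_range` (the planted DMBs), while the remaining tumor
#' levels equal the normal level plus noise.
#'
#' @param spec a [simulation_spec()].
#' @param seed seed for this tissue pair; defaults to the spec seed so the
#'   default pair is a pure function of the spec. Distinct seeds give
#'   distinct patients on the same panel.
#' @param patient_id identifier attached to the profiles.
#' @return List with `tumor` and `normal` (`tissue_methylome`) and `truth`
#'   (character vector of planted block ids).
#' @export
simulate_tissue_pair <- function(spec, seed = spec$seed, patient_id = "sim_patient") {
  bp <- sim_block_params(spec)
  with_seed(seed_plus(seed, 1), {
    prior_mean <- bp$p / (bp$p + bp$q)
    normal <- clip01(prior_mean + stats::rnorm(spec$n_blocks, 0, spec$normal_noise_sd))
    planted <- sort(sample.int(spec$n_blocks, spec$n_dmb_true))
    tumor <- clip01(normal + stats::rnorm(spec$n_blocks, 0, spec$tumor_noise_sd))
    tumor[planted] <- stats::runif(spec$n_dmb_true, spec$tumor_range[1], spec$tumor_range[2])
    list(tumor = tissue_methylome(patient_id, bp$block_id, tumor,
                                  rep(spec$tissue_depth, spec$n_blocks), "tumor"),
         normal = tissue_methylome(patient_id, bp$block_id, normal,
                                   rep(spec$tissue_depth, spec$n_blocks), "adjacent_normal"),
         truth = bp$block_id[planted])
  })
}

# one plasma sample: beta0 ~ Beta(p, q); beta from the mixture; N negative
# binomial; M ~ Binomial(N, beta). Draw order is fixed so alpha = gamma = 0
# reproduces a healthy sample byte-identically at matched seeds.
draw_plasma_counts <- function(sample_id, alpha, gamma, beta_t, beta_n, bp, spec, seed) {
  with_seed(seed, {
    beta0 <- stats::rbeta(spec$n_blocks, bp$p, bp$q)
    beta <- alpha * beta_t + gamma * beta_n + (1 - alpha - gamma) * beta0
    N <- stats::rnbinom(spec$n_blocks, mu = spec$depth_mean, size = spec$depth_dispersion)
    M <- stats::rbinom(spec$n_blocks, N, beta)
    block_counts(sample_id, bp$block_id, N, M)
  })
}

#' Simulate healthy-donor plasma samples
#'
#' Background-only plasma: per sample and block, the methylation level is
#' drawn from the block's true Beta(p, q), depth from the negative-binomial
#' model, methylated counts binomially. Sample `i` uses seed
#' `spec$seed + 1000 + i`.
#'
#' @param spec a [simulation_spec()].
#' @param n_samples number of healthy samples.
#' @return List with `samples` (named list of `block_counts`) and `prior`
#'   (the true `background_prior`).
#' @export
simulate_healthy_plasma <- function(spec, n_samples) {
  bp <- sim_block_params(spec)
  zero <- numeric(spec$n_blocks)
  samples <- lapply(seq_len(n_samples), function(i) {
    draw_plasma_counts(sprintf("healthy%03d", i), 0, 0, zero, zero, bp, spec,
                       seed_plus(spec$seed, 1000 + i))
  })
  names(samples) <- vapply(samples, attr, "", "sample_id")
  list(samples = samples, prior = true_background_prior(spec))
}

#' Simulate a plasma mixture at specified (alpha, gamma)
#'
#' Generates one plasma sample whose counts follow the generative model the
#' scorer assumes: background level from the true prior, mixed with the
#' given tissue profiles at ctDNA fraction `alpha` and adjacent-normal
#' fraction `gamma`.
#'
#' @inheritParams mixture_mean
#' @param tumor,normal `tissue_methylome` objects (e.g. from
#'   [simulate_tissue_pair()]).
#' @param true_prior a `background_prior` holding the generating shapes.
#' @param spec a [simulation_spec()] (depth model and panel size).
#' @param seed sample seed; `spec$seed + 1000 + i` reproduces healthy
#'   sample `i` exactly when `alpha = gamma = 0`.
#' @param sample_id identifier for the generated sample.
#' @return A `block_counts`.
#' @export
simulate_plasma_mixture <- function(alpha, gamma, tumor, normal, true_prior, spec,
                                    seed = seed_plus(spec$seed, 2000),
                                    sample_id = "mixture") {
  if (alpha < 0 || gamma < 0 || alpha + gamma >= 1) {
    stop_timmrd("constraint violated: need alpha >= 0, gamma >= 0, alpha + gamma < 1")
  }
  bp <- true_prior[match(tumor$block_id, true_prior$block_id), c("block_id", "p", "q")]
  if (anyNA(bp$p)) stop_timmrd("true_prior does not cover the tissue blocks")
  draw_plasma_counts(sample_id, alpha, gamma, tumor$level, normal$level, bp, spec, seed)
}

#' Simulate an in-silico dilution series
#'
#' For each tumor fraction, generates `reps` plasma mixtures with
#' `gamma = 0` against one fixed simulated tissue pair, labelled with the
#' true fraction — the in-silico analogue of serial spike-in dilutions used
#' to probe the limit of detection.
#'
#' @param fractions numeric vector of tumor fractions (0 allowed).
#' @param reps replicates per fraction.
#' @param spec a [simulation_spec()].
#' @return List with `samples` (named list of `block_counts`), `labels`
#'   (data frame `sample_id, true_fraction, rep`), `tissue` (the pair) and
#'   `prior` (true `background_prior`).
#' @export
simulate_dilution_series <- function(fractions, reps, spec) {
  if (any(fractions < 0 | fractions >= 1)) stop_timmrd("fractions must lie in [0, 1)")
  tissue <- simulate_tissue_pair(spec)
  prior <- true_background_prior(spec)
  labels <- expand.grid(rep = seq_len(reps), true_fraction = fractions,
                        KEEP.OUT.ATTRS = FALSE)
  labels$sample_id <- sprintf("dil_f%g_r%02d", labels$true_fraction, labels$rep)
  # common random numbers: replicate r shares its seed across fractions, so
  # power curves over the fraction grid are coupled (variance reduction)
  samples <- lapply(seq_len(nrow(labels)), function(k) {
    simulate_plasma_mixture(labels$true_fraction[k], 0, tissue$tumor, tissue$normal,
                            prior, spec,
                            seed = seed_plus(spec$seed, 20000 + labels$rep[k]),
                            sample_id = labels$sample_id[k])
  })
  names(samples) <- labels$sample_id
  list(samples = samples, labels = labels[, c("sample_id", "true_fraction", "rep")],
       tissue = tissue, prior = prior)
}

#' Longitudinal cohort specification
#'
#' Defines the perioperative sampling grid and the disease dynamics of a
#' synthetic surveillance cohort. Blood is drawn preoperatively (`A`,
#' day -1), shortly after surgery (`B`, day 3), about one month after
#' surgery (`C`), and at regular follow-up visits (`F`). After surgery the
#' ctDNA fraction of cured patients drops to zero; in relapsing patients the
#' baseline fraction decays with a short half-life (cfDNA clearance) and
#' re-emerges exponentially ahead of the relapse day, so samples within
#' roughly one lead time of relapse carry signal.
#' Mutation status is emulated as a noisy monotone transform of the ctDNA
#' fraction with read-sampling dropout and a detection floor, reflecting the
#' lower per-locus sensitivity of mutation assays at low burden.
#'
#' @param n_patients cohort size.
#' @param relapse_fraction fraction of patients who relapse.
#' @param baseline_alpha_range log-uniform range of preoperative ctDNA
#'   fractions.
#' @param relapse_day_range uniform range (days) of relapse days.
#' @param plasma_c_day day of the `C` draw.
#' @param followup_interval_days,followup_end_days regular `F` draws at
#'   `seq(followup_interval_days, followup_end_days, by = followup_interval_days)`.
#' @param alpha_relapse ctDNA fraction reached on the relapse day.
#' @param lead_time_mean_days,lead_time_sd_days Gaussian lead-time draw
#'   (days, truncated at 30): the regrowth time-constant is the drawn lead
#'   time divided by 2.5, so the fraction crosses the detectability range
#'   about one lead time before relapse.
#' @param perioperative_halflife_days post-surgical decay half-life of the
#'   baseline fraction.
#' @param mut_af_ratio expected maxAF per unit ctDNA fraction (about 0.5
#'   for a clonal heterozygous variant).
#' @param mut_logit_sd logit-scale noise of the allele fraction.
#' @param mut_depth effective unique read depth of the mutation assay.
#' @param mut_min_reads minimum supporting reads to call a mutation.
#' @param mut_af_floor minimum reportable allele fraction.
#' @param seed integer master seed for the cohort.
#' @return A list of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(n_patients = 200L, relapse_fraction = 0.25,
                              baseline_alpha_range = c(0.005, 0.05),
                              relapse_day_range = c(240L, 540L),
                              plasma_c_day = 36L,
                              followup_interval_days = 60L,
                              followup_end_days = 540L,
                              alpha_relapse = 0.03,
                              lead_time_mean_days = 250,
                              lead_time_sd_days = 60,
                              perioperative_halflife_days = 1,
                              mut_af_ratio = 0.5, mut_logit_sd = 0.5,
                              mut_depth = 800L, mut_min_reads = 2L,
                              mut_af_floor = 5e-4,
                              seed = 1L) {
  if (relapse_fraction < 0 || relapse_fraction > 1) {
    stop_timmrd("relapse_fraction must lie in [0, 1]")
  }
  if (followup_interval_days <= 0 || followup_end_days < followup_interval_days) {
    stop_timmrd("inconsistent follow-up day grid")
  }
  structure(list(n_patients = as.integer(n_patients), relapse_fraction = relapse_fraction,
                 baseline_alpha_range = baseline_alpha_range,
                 relapse_day_range = as.integer(relapse_day_range),
                 plasma_c_day = as.integer(plasma_c_day),
                 followup_interval_days = as.integer(followup_interval_days),
                 followup_end_days = as.integer(followup_end_days),
                 alpha_relapse = alpha_relapse,
                 lead_time_mean_days = lead_time_mean_days,
                 lead_time_sd_days = lead_time_sd_days,
                 perioperative_halflife_days = perioperative_halflife_days,
                 mut_af_ratio = mut_af_ratio, mut_logit_sd = mut_logit_sd,
                 mut_depth = as.integer(mut_depth), mut_min_reads = as.integer(mut_min_reads),
                 mut_af_floor = mut_af_floor, seed = as.integer(seed)),
            class = "longitudinal_spec")
}

# noisy monotone transform of the true ctDNA fraction into an observed maxAF
# with Poisson read sampling, a minimum read count and an AF floor
draw_maxaf <- function(alpha_t, lspec) {
  if (alpha_t <= 0) return(0)
  af_true <- stats::plogis(stats::qlogis(clip01(alpha_t * lspec$mut_af_ratio, 1e-8)) +
                             stats::rnorm(1, 0, lspec$mut_logit_sd))
  reads <- stats::rpois(1, af_true * lspec$mut_depth)
  af_obs <- reads / lspec$mut_depth
  if (reads >= lspec$mut_min_reads && af_obs >= lspec$mut_af_floor) af_obs else 0
}

#' Simulate a longitudinal surveillance cohort
#'
#' Per patient: a tissue pair on the shared panel, a baseline ctDNA
#' fraction, a relapse label and day, and plasma samples on the
#' perioperative/follow-up grid (samples after the relapse day are not
#' drawn). Each sample carries generated methylation counts, the true
#' ctDNA fraction and an emulated maxAF. Fully deterministic per seed.
#'
#' @param lspec a [longitudinal_spec()].
#' @param spec a [simulation_spec()] describing the panel.
#' @return A list of class `timmrd_cohort` with elements `patients` (each a
#'   list: `patient_id`, `tissue`, `samples`, `manifest`, `relapsed`,
#'   `relapse_day`, `dfs_days`), `lspec` and `spec`.
#' @export
simulate_longitudinal_cohort <- function(lspec, spec) {
  bp <- sim_block_params(spec)
  patients <- lapply(seq_len(lspec$n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    pars <- with_seed(seed_plus(lspec$seed, 10000 + i), {
      list(relapsed = stats::runif(1) < lspec$relapse_fraction,
           baseline_alpha = exp(stats::runif(1, log(lspec$baseline_alpha_range[1]),
                                             log(lspec$baseline_alpha_range[2]))),
           relapse_day = round(stats::runif(1, lspec$relapse_day_range[1],
                                            lspec$relapse_day_range[2])),
           lead = max(30, stats::rnorm(1, lspec$lead_time_mean_days,
                                       lspec$lead_time_sd_days)))
    })
    tau <- pars$lead / 2.5
    days <- c(-1L, 3L, lspec$plasma_c_day,
              seq(lspec$followup_interval_days, lspec$followup_end_days,
                  by = lspec$followup_interval_days))
    labels <- c("A", "B", "C", rep("F", length(days) - 3L))
    if (pars$relapsed) {
      keep <- days <= pars$relapse_day
      days <- days[keep]; labels <- labels[keep]
    }
    alpha_t <- vapply(days, function(t) {
      if (t < 0) return(pars$baseline_alpha)
      if (!pars$relapsed) return(0)  # complete resection: the ctDNA source is gone
      resid <- pars$baseline_alpha * 2^(-t / lspec$perioperative_halflife_days)
      rel <- lspec$alpha_relapse * exp(-(pars$relapse_day - t) / tau)
      min(0.9, resid + rel)
    }, 0)
    tissue <- simulate_tissue_pair(spec, seed = seed_plus(lspec$seed, 20000 + i),
                                   patient_id = pid)
    sample_ids <- sprintf("%s_%s_d%d", pid, labels, days)
    samples <- lapply(seq_along(days), function(s) {
      draw_plasma_counts(sample_ids[s], alpha_t[s], 0, tissue$tumor$level,
                         tissue$normal$level, bp, spec,
                         seed_plus(lspec$seed, 100000 + 100 * i + s))
    })
    names(samples) <- sample_ids
    max_af <- vapply(seq_along(days), function(s) {
      with_seed(seed_plus(lspec$seed, 400000 + 100 * i + s), draw_maxaf(alpha_t[s], lspec))
    }, 0)
    manifest <- data.frame(sample_id = sample_ids, patient_id = pid,
                           timepoint_label = labels, day_from_surgery = days,
                           true_alpha = alpha_t, max_af = max_af,
                           stringsAsFactors = FALSE)
    list(patient_id = pid, tissue = tissue, samples = samples, manifest = manifest,
         relapsed = pars$relapsed,
         relapse_day = if (pars$relapsed) pars$relapse_day else NA_integer_,
         dfs_days = if (pars$relapsed) pars$relapse_day else lspec$followup_end_days)
  })
  names(patients) <- vapply(patients, `[[`, "", "patient_id")
  structure(list(patients = patients, lspec = lspec, spec = spec),
            class = "timmrd_cohort")
}
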