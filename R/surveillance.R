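#' Build a patient's surveillance timeline
#'
#' Merges per-sample summaries and fits into one day-sorted record with the
#' patient's relapse annotation. `dfs_days` is the disease-free survival in
#' days: surgery to confirmed recurrence, or to last follow-up for
#' censored patients.
#'
#' @param samples data frame with columns `sample_id, timepoint_label,
#'   day_from_surgery` and optionally `methyl_mean, max_af`.
#' @param fits named list of `timmrd_fit` keyed by sample id (entries may be
#'   missing for unscored samples).
#' @param clinical list or one-row data frame with `patient_id`, `relapsed`,
#'   `relapse_day` (required iff relapsed) and `dfs_days`.
#' @return An object of class `patient_timeline`.
#' @export
build_timeline <- function(samples, fits, clinical) {
  clinical <- as.list(clinical)
  if (is.null(clinical$patient_id)) stop_timmrd("clinical record lacks patient_id")
  relapsed <- isTRUE(clinical$relapsed)
  relapse_day <- clinical$relapse_day
  if (relapsed && (is.null(relapse_day) || is.na(relapse_day))) {
    stop_timmrd("patient '%s' marked relapsed without a relapse_day", clinical$patient_id)
  }
  if (!relapsed) relapse_day <- NA_integer_
  dfs <- clinical$dfs_days %||% (if (relapsed) relapse_day else NA_integer_)
  if (!is.na(dfs) && dfs < 0) stop_timmrd("dfs_days must be non-negative")
  if (nrow(samples)) {
    check_cols(samples, c("sample_id", "timepoint_label", "day_from_surgery"), "timeline samples")
    if (!is.null(samples$patient_id) &&
        any(samples$patient_id != clinical$patient_id)) {
      stop_timmrd("sample records do not all belong to patient '%s'", clinical$patient_id)
    }
    pick <- function(f, field, proto) if (is.null(f)) proto else f[[field]]
    samples$alpha_hat <- vapply(samples$sample_id, function(id) pick(fits[[id]], "alpha_hat", NA_real_), 0)
    samples$gamma_hat <- vapply(samples$sample_id, function(id) pick(fits[[id]], "gamma_hat", NA_real_), 0)
    samples$score <- vapply(samples$sample_id, function(id) pick(fits[[id]], "score", NA_real_), 0)
    samples$call <- vapply(samples$sample_id, function(id) pick(fits[[id]], "call", NA_character_), "")
    samples <- samples[order(samples$day_from_surgery), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(patient_id = as.character(clinical$patient_id), samples = samples,
                 relapsed = relapsed, relapse_day = relapse_day, dfs_days = dfs),
            class = "patient_timeline")
}

#' Score a simulated longitudinal cohort end to end
#'
#' Runs the full pipeline on a [simulate_longitudinal_cohort()] object:
#' fits the background prior from simulated healthy plasma (unless a prior
#' is supplied), selects each patient's DMB panel from their tissue pair,
#' fits the mixture for every plasma sample, and assembles
#' `patient_timeline`s. Samples whose fit fails are recorded as unscored
#' (call `"low"`, score `NA`) with a warning.
#'
#' @param cohort a `timmrd_cohort`.
#' @param prior optional `background_prior`; fitted from `healthy_n`
#'   simulated healthy samples when `NULL`.
#' @param opts a [scoring_options()] list.
#' @param healthy_n number of healthy samples for prior fitting.
#' @param ... passed to [select_patient_dmbs()].
#' @return Named list of `patient_timeline`s.
#' @export
score_cohort <- function(cohort, prior = NULL, opts = scoring_options(),
                         healthy_n = 24L, ...) {
  stopifnot(inherits(cohort, "timmrd_cohort"))
  if (is.null(prior)) {
    healthy <- simulate_healthy_plasma(cohort$spec, healthy_n)
    prior <- fit_panel_prior(healthy$samples, simulate_block_defs(cohort$spec))
  }
  n_failed <- 0L
  timelines <- lapply(cohort$patients, function(pt) {
    panel <- select_patient_dmbs(pt$tissue$tumor, pt$tissue$normal, prior, ...)
    fits <- lapply(pt$samples, function(cnt) {
      tryCatch(fit_timmrd(panel, cnt, prior, opts), error = function(e) {
        n_failed <<- n_failed + 1L
        structure(list(alpha_hat = NA_real_, gamma_hat = NA_real_,
                       loglik_full = NA_real_, loglik_null = NA_real_,
                       score = NA_real_, call = "low", n_blocks_used = 0L,
                       converged = FALSE, alpha_se = NA_real_,
                       threshold = classification_threshold(opts$percentile),
                       percentile = opts$percentile),
                  class = "timmrd_fit")
      })
    })
    sm <- pt$manifest
    sm$methyl_mean <- vapply(pt$samples, compute_methylmean, 0)
    build_timeline(sm, fits,
                   list(patient_id = pt$patient_id, relapsed = pt$relapsed,
                        relapse_day = pt$relapse_day, dfs_days = pt$dfs_days))
  })
  if (n_failed > 0L) warning(sprintf("%d sample fit(s) failed and were recorded as unscored", n_failed))
  timelines
}

#' Lead time of molecular detection before confirmed relapse
#'
#' Under the default `first_positive` rule: days between the earliest
#' postoperative timMRD-high sample taken on or before the relapse day and
#' the relapse day itself. `NA` when no positive sample precedes relapse
#' (such patients are excluded from average lead times). The
#' `last_negative_to_relapse` rule instead measures from the last
#' timMRD-low sample before relapse, an upper bound on the detection lead.
#'
#' @param timeline a `patient_timeline` of a relapsed patient.
#' @param rule `"first_positive"` (default) or `"last_negative_to_relapse"`.
#' @return Days (non-negative) or `NA`.
#' @export
lead_time <- function(timeline, rule = c("first_positive", "last_negative_to_relapse")) {
  rule <- match.arg(rule)
  if (!isTRUE(timeline$relapsed)) {
    stop_timmrd("lead time is defined only for relapsed patients ('%s')", timeline$patient_id)
  }
  s <- timeline$samples
  s <- s[s$day_from_surgery >= 0 & s$day_from_surgery <= timeline$relapse_day &
           !is.na(s$call), , drop = FALSE]
  if (rule == "first_positive") {
    pos <- s$day_from_surgery[s$call == "high"]
    if (!length(pos)) return(NA_real_)
    timeline$relapse_day - min(pos)
  } else {
    neg <- s$day_from_surgery[s$call == "low"]
    if (!length(neg)) return(NA_real_)
    timeline$relapse_day - max(neg)
  }
}

# horizon sample selection shared by horizon_confusion and roc_over_thresholds:
# relapsed patients contribute their last postoperative sample taken at or
# before relapse_day - horizon_days; non-relapsed their last follow-up sample
horizon_sample <- function(timeline, horizon_days) {
  s <- timeline$samples
  s <- s[s$day_from_surgery >= 0, , drop = FALSE]
  if (!nrow(s)) return(NULL)
  if (isTRUE(timeline$relapsed)) {
    s <- s[s$day_from_surgery <= timeline$relapse_day - horizon_days, , drop = FALSE]
    if (!nrow(s)) return(NULL)
  }
  s[which.max(s$day_from_surgery), , drop = FALSE]
}

#' Confusion matrix for relapse prediction at a fixed horizon
#'
#' Each relapsed patient is evaluated at their last sample taken at least
#' `horizon_days` before clinical confirmation of relapse; non-relapsed
#' patients at their last follow-up sample. A patient is test-positive when
#' that sample is timMRD-high (`assay = "timmrd"`) or has `maxAF > 0`
#' (`assay = "mutation"`). Patients with no evaluable sample are dropped
#' (their number is reported).
#'
#' @param timelines list of `patient_timeline`s.
#' @param horizon_days evaluation horizon in days before relapse.
#' @param assay `"timmrd"` or `"mutation"`.
#' @return A list of class `confusion_summary`: counts `tp, fp, tn, fn`,
#'   metrics `sensitivity, specificity, ppv, npv` (NA on zero denominators),
#'   and `n_dropped`.
#' @export
horizon_confusion <- function(timelines, horizon_days = 120L,
                              assay = c("timmrd", "mutation")) {
  assay <- match.arg(assay)
  tp <- fp <- tn <- fn <- dropped <- 0L
  for (tl in timelines) {
    s <- horizon_sample(tl, horizon_days)
    if (is.null(s)) { dropped <- dropped + 1L; next }
    pos <- if (assay == "timmrd") {
      !is.na(s$call) && s$call == "high"
    } else {
      !is.na(s$max_af) && s$max_af > 0
    }
    if (isTRUE(tl$relapsed)) {
      if (pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  if (tp + fp + tn + fn == 0L) stop_timmrd("no evaluable patient at horizon %d", horizon_days)
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = frac(tp, tp + fn), specificity = frac(tn, tn + fp),
                 ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn),
                 n_dropped = dropped, assay = assay, horizon_days = horizon_days),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("%s assay at %d-day horizon: tp=%d fp=%d tn=%d fn=%d (dropped %d)\n",
              x$assay, x$horizon_days, x$tp, x$fp, x$tn, x$fn, x$n_dropped))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, ppv %.3f, npv %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' ROC curve over timMRD-score thresholds at a fixed horizon
#'
#' Sweeps the classification threshold over all observed per-patient
#' horizon-sample scores, emitting `(1 - specificity, sensitivity)` points
#' and the trapezoidal area under the curve.
#'
#' @param timelines list of `patient_timeline`s (at least one relapsed and
#'   one non-relapsed with scores).
#' @param horizon_days evaluation horizon in days.
#' @return List with `points` (data frame `threshold, fpr, sensitivity`)
#'   and `auc`.
#' @export
roc_over_thresholds <- function(timelines, horizon_days = 120L) {
  score <- label <- numeric(0)
  for (tl in timelines) {
    s <- horizon_sample(tl, horizon_days)
    if (is.null(s) || is.na(s$score)) next
    score <- c(score, s$score)
    label <- c(label, as.integer(isTRUE(tl$relapsed)))
  }
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_timmrd("ROC needs both relapsed and non-relapsed patients with scores")
  }
  thr <- c(-Inf, sort(unique(score)))
  pts <- t(vapply(thr, function(th) {
    c(fpr = sum(score[label == 0L] > th) / n0,
      sens = sum(score[label == 1L] > th) / n1)
  }, c(fpr = 0, sens = 0)))
  pts <- data.frame(threshold = thr, fpr = pts[, "fpr"], sensitivity = pts[, "sens"])
  ord <- order(pts$fpr, pts$sensitivity)
  x <- c(pts$fpr[ord]); y <- c(pts$sensitivity[ord])
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value with fixed margins (sum of hypergeometric
#' probabilities no larger than the observed table's). Thin wrapper over
#' the standard exact test, exposed with the row-wise table layout
#' `[[a, b], [c, d]]`.
#'
#' @param a,b,c,d non-negative integer cell counts (first row `a, b`;
#'   second row `c, d`).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop_timmrd("cell counts must be non-negative")
  if (sum(cells) == 0) stop_timmrd("empty 2x2 table")
  stats::fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))$p.value
}

#' Export a survival-ready table
#'
#' One row per patient with `patient_id, dfs_days, event, group`, suitable
#' for standard survival tooling (Kaplan-Meier, log-rank, Cox). Grouping
#' rules: `timmrd_call` labels a patient `high` when the selected sample(s)
#' are timMRD-high, `mutation_status` uses `maxAF > 0`. Timepoint rules:
#' `"plasma_bc"` combines the B and C draws, taking the worse (positive)
#' of the two when both exist; `"last_followup"` uses the last
#' postoperative sample.
#'
#' @param timelines list of `patient_timeline`s.
#' @param grouping `"timmrd_call"` or `"mutation_status"`.
#' @param at `"plasma_bc"` or `"last_followup"`.
#' @param path optional TSV output path.
#' @return The table (invisibly written to `path` when given).
#' @export
export_survival_table <- function(timelines, grouping = c("timmrd_call", "mutation_status"),
                                  at = c("plasma_bc", "last_followup"), path = NULL) {
  grouping <- match.arg(grouping)
  at <- tryCatch(match.arg(at), error = function(e) {
    stop_timmrd("unknown timepoint rule '%s'", at[1L])
  })
  rows <- lapply(timelines, function(tl) {
    s <- tl$samples[tl$samples$day_from_surgery >= 0, , drop = FALSE]
    s <- switch(at,
                plasma_bc = s[s$timepoint_label %in% c("B", "C"), , drop = FALSE],
                last_followup = if (nrow(s)) s[which.max(s$day_from_surgery), , drop = FALSE] else s)
    pos <- if (grouping == "timmrd_call") {
      any(!is.na(s$call) & s$call == "high")
    } else {
      any(!is.na(s$max_af) & s$max_af > 0)
    }
    data.frame(patient_id = tl$patient_id, dfs_days = tl$dfs_days,
               event = as.integer(isTRUE(tl$relapsed)),
               group = if (pos) "high" else "low", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
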