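#' Discover cohort-level differentially methylated blocks
#'
#' Per block, a paired two-tailed Wilcoxon signed-rank test compares tumor
#' versus matched adjacent-normal methylation levels across patients;
#' p-values are Benjamini-Hochberg corrected across blocks. Blocks pass when
#' the absolute mean paired difference is at least `effect_min` and the
#' corrected q-value is at most `q_max`. Candidates are ranked by absolute
#' effect size (ties broken by `block_id`) and annotated with direction
#' (`hyper` when tumor exceeds normal).
#'
#' @param tumors,normals lists of `tissue_methylome`, patient-matched by
#'   position (at least 3 pairs); `names()` are compared when present.
#' @param effect_min minimum absolute mean paired difference.
#' @param q_max maximum BH-adjusted q-value.
#' @return Data frame of class `dmb_candidates` with columns `block_id,
#'   mean_tumor, mean_normal, effect_size, p_value, q_value, direction`.
#' @export
discover_cohort_dmbs <- function(tumors, normals, effect_min = 0.1, q_max = 0.05) {
  if (length(tumors) != length(normals)) {
    stop_timmrd("tumor and normal collections must be patient-matched (%d vs %d)",
                length(tumors), length(normals))
  }
  if (!is.null(names(tumors)) && !is.null(names(normals)) &&
      !identical(names(tumors), names(normals))) {
    stop_timmrd("tumor and normal collections are not matched by patient id")
  }
  if (length(tumors) < 3L) {
    stop_timmrd("need at least 3 tumor/normal pairs (got %d)", length(tumors))
  }
  ids <- sort(unique(unlist(lapply(tumors, function(d) d$block_id))))
  tum <- sapply(tumors, function(d) d$level[match(ids, d$block_id)])
  nor <- sapply(normals, function(d) d$level[match(ids, d$block_id)])
  res <- lapply(seq_along(ids), function(i) {
    t_i <- tum[i, ]; n_i <- nor[i, ]
    ok <- !is.na(t_i) & !is.na(n_i)
    if (sum(ok) < 3L) return(NULL)
    d <- t_i[ok] - n_i[ok]
    pv <- if (all(d == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(t_i[ok], n_i[ok], paired = TRUE,
                                          alternative = "two.sided")$p.value)
    }
    data.frame(block_id = ids[i], mean_tumor = mean(t_i[ok]), mean_normal = mean(n_i[ok]),
               effect_size = mean(d), p_value = pv, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) stop_timmrd("no block with >= 3 evaluable pairs")
  res$p_value[is.na(res$p_value)] <- 1
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[abs(res$effect_size) >= effect_min & res$q_value <= q_max, , drop = FALSE]
  res$direction <- ifelse(res$effect_size >= 0, "hyper", "hypo")
  res <- res[order(-abs(res$effect_size), res$block_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dmb_candidates", "data.frame")
  res
}

#' Select a patient's personal DMB panel
#'
#' Tumor-informed marker selection: keep blocks where (i) the patient's tumor
#' level exceeds the background prior mean `p/(p+q)` by at least
#' `delta_prior`, (ii) the tumor level exceeds the matched adjacent-normal
#' level by at least `delta_normal`, and (iii) the prior concentration
#' `p + q` is at least `concentration_min` (i.e. the background is stably
#' characterised). Blocks are ranked by tumor-minus-prior-mean margin
#' (ties by `block_id`) and truncated to `m_max`. With
#' `direction = "hypo"` all inequalities are mirrored.
#'
#' @param tumor,normal `tissue_methylome` objects for the patient.
#' @param prior a `background_prior`.
#' @param cohort_dmbs optional character vector of block ids; when given the
#'   candidate set is restricted to it.
#' @param delta_prior minimum tumor-minus-prior-mean margin.
#' @param delta_normal minimum tumor-minus-normal margin.
#' @param m_max maximum panel size.
#' @param concentration_min minimum prior concentration `p + q`.
#' @param direction `"hyper"` (default) or `"hypo"`.
#' @return A `patient_panel` data frame with columns
#'   `block_id, beta_t, beta_n` and attribute `patient_id`.
#' @export
select_patient_dmbs <- function(tumor, normal, prior, cohort_dmbs = NULL,
                                delta_prior = 0.2, delta_normal = 0.1,
                                m_max = 5000L, concentration_min = 10,
                                direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  prior <- validate_background_prior(prior)
  df <- merge(data.frame(block_id = tumor$block_id, beta_t = tumor$level,
                         stringsAsFactors = FALSE),
              data.frame(block_id = normal$block_id, beta_n = normal$level,
                         stringsAsFactors = FALSE),
              by = "block_id")
  df <- merge(df, prior[, c("block_id", "p", "q")], by = "block_id")
  if (!is.null(cohort_dmbs)) df <- df[df$block_id %in% cohort_dmbs, , drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (!nrow(df)) stop_timmrd("patient '%s' unscoreable: no candidate block with tumor, normal and prior data",
                             attr(tumor, "sample_id") %||% "?")
  prior_mean <- df$p / (df$p + df$q)
  margin <- if (direction == "hyper") df$beta_t - prior_mean else prior_mean - df$beta_t
  tn <- if (direction == "hyper") df$beta_t - df$beta_n else df$beta_n - df$beta_t
  keep <- margin >= delta_prior & tn >= delta_normal & (df$p + df$q) >= concentration_min
  df <- df[keep, , drop = FALSE]
  margin <- margin[keep]
  if (!nrow(df)) {
    stop_timmrd("patient '%s' unscoreable: no block passes the DMB selection margins",
                attr(tumor, "sample_id") %||% "?")
  }
  ord <- order(-margin, df$block_id)
  df <- df[utils::head(ord, m_max), c("block_id", "beta_t", "beta_n"), drop = FALSE]
  rownames(df) <- NULL
  patient_panel(attr(tumor, "sample_id") %||% "patient", df$block_id, df$beta_t, df$beta_n,
                direction = direction)
}

#' Construct a patient panel
#'
#' @param patient_id single patient identifier.
#' @param block_id character vector of selected DMBs.
#' @param beta_t,beta_n tumor and adjacent-normal methylation levels per block.
#' @param direction panel direction, `"hyper"` or `"hypo"`.
#' @return A `patient_panel` data frame; `m = nrow()` is the number of DMBs.
#' @export
patient_panel <- function(patient_id, block_id, beta_t, beta_n, direction = "hyper") {
  df <- data.frame(block_id = as.character(block_id), beta_t = as.numeric(beta_t),
                   beta_n = as.numeric(beta_n), stringsAsFactors = FALSE)
  if (!nrow(df)) stop_timmrd("a patient panel needs at least one block")
  if (any(!is_fraction(df$beta_t)) || any(!is_fraction(df$beta_n))) {
    stop_timmrd("panel methylation levels must lie in [0,1]")
  }
  if (direction == "hyper" && any(df$beta_n > df$beta_t)) {
    stop_timmrd("hyper-directional panel requires beta_n <= beta_t for every block")
  }
  if (anyDuplicated(df$block_id)) stop_timmrd("duplicate block_id in panel for '%s'", patient_id)
  attr(df, "patient_id") <- as.character(patient_id)
  attr(df, "direction") <- direction
  class(df) <- c("patient_panel", "data.frame")
  df
}

#' Hypermethylation ratio of a tissue sample
#'
#' Fraction of evaluable blocks (level defined, prior present) whose
#' methylation level exceeds the background prior mean by more than `margin`.
#'
#' @param tissue a `tissue_methylome`.
#' @param prior a `background_prior`.
#' @param margin excess over the prior mean required to count a block.
#' @return A fraction in `[0, 1]`.
#' @export
hypermethylation_ratio <- function(tissue, prior, margin = 0.2) {
  prior <- validate_background_prior(prior)
  df <- merge(data.frame(block_id = tissue$block_id, level = tissue$level,
                         stringsAsFactors = FALSE),
              prior[, c("block_id", "p", "q")], by = "block_id")
  df <- df[!is.na(df$level), , drop = FALSE]
  if (!nrow(df)) stop_timmrd("hypermethylation ratio undefined: no evaluable block")
  mean(df$level > df$p / (df$p + df$q) + margin)
}

#' Read / write patient panels
#'
#' TSV with header `patient_id, block_id, beta_t, beta_n`.
#'
#' @param path file path.
#' @return `read_patient_panels` returns a named list of `patient_panel`s.
#' @export
read_patient_panels <- function(path) {
  if (!file.exists(path)) stop_timmrd("panel table not found: '%s'", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_cols(df, c("patient_id", "block_id", "beta_t", "beta_n"), "panel table", path)
  out <- lapply(split(df, df$patient_id), function(d) {
    patient_panel(d$patient_id[1L], d$block_id, d$beta_t, d$beta_n)
  })
  out[unique(df$patient_id)]
}

#' @param panels a `patient_panel` or list of them.
#' @rdname read_patient_panels
#' @export
write_patient_panels <- function(panels, path) {
  if (inherits(panels, "patient_panel")) panels <- list(panels)
  rows <- lapply(panels, function(d) {
    data.frame(patient_id = attr(d, "patient_id"), block_id = d$block_id,
               beta_t = d$beta_t, beta_n = d$beta_n, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DMB candidate table
#'
#' @param candidates a `dmb_candidates` data frame.
#' @param path output path.
#' @export
write_dmb_candidates <- function(candidates, path) {
  utils::write.table(candidates[, c("block_id", "effect_size", "p_value", "q_value", "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
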