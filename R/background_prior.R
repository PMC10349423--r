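#' Fit a beta prior to one block's background methylation ratios
#'
#' The background methylation level of a block in healthy plasma is modelled
#' as Beta(p, q). Shapes are estimated by the method of moments: with sample
#' mean `m` and unbiased variance `v`, the common concentration is
#' `c = m (1 - m) / v - 1`, giving `p = m c`, `q = (1 - m) c`. Degenerate
#' inputs (near-zero variance, or non-positive `c`) fall back to a
#' pseudocount fit `p = m c0 + eps`, `q = (1 - m) c0 + eps`. Ratios exactly
#' 0 or 1 are clipped inward before fitting; all-zero blocks are common in
#' hypermethylation panels and would otherwise yield infinite concentration.
#'
#' @param ratios numeric vector of methylation fractions in `[0, 1]`,
#'   at least two values.
#' @param clip inward clipping applied to ratios at 0 or 1.
#' @param variance_floor variance at or below which the moment fit is
#'   abandoned.
#' @param c0 fallback concentration.
#' @param eps fallback pseudocount added to both shapes.
#' @return List with `p`, `q` (positive shapes) and `fit_method`
#'   (`"moments"` or `"pseudocount_fallback"`).
#' @export
fit_block_prior <- function(ratios, clip = 1e-4, variance_floor = 1e-8,
                            c0 = 100, eps = 0.5) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2L) stop_timmrd("need at least 2 ratios to fit a block prior")
  if (any(!is_fraction(ratios))) stop_timmrd("ratios must lie in [0,1]")
  r <- clip01(ratios, clip)
  m <- mean(r)
  v <- stats::var(r)
  if (v <= variance_floor) {
    return(list(p = m * c0 + eps, q = (1 - m) * c0 + eps,
                fit_method = "pseudocount_fallback"))
  }
  conc <- m * (1 - m) / v - 1
  if (conc <= 0) {
    return(list(p = m * c0 + eps, q = (1 - m) * c0 + eps,
                fit_method = "pseudocount_fallback"))
  }
  list(p = m * conc, q = (1 - m) * conc, fit_method = "moments")
}

#' Fit the panel-wide background prior from healthy plasma
#'
#' For each block, gathers the per-sample ratios `n_meth / n_total` over
#' healthy samples with depth at least `min_depth` and fits a beta prior via
#' [fit_block_prior()]. Blocks with fewer than two usable samples get the
#' pseudocount fallback centred on the panel-wide pooled mean ratio.
#'
#' @param healthy list of `block_counts` from healthy-donor plasma
#'   (at least 2 samples).
#' @param blocks `block_defs` for the panel.
#' @param min_depth minimum depth for a sample to contribute to a block.
#' @param ... passed on to [fit_block_prior()].
#' @return A `background_prior` data frame with columns
#'   `block_id, p, q, n_samples_used, fit_method`.
#' @export
fit_panel_prior <- function(healthy, blocks, min_depth = 1L, ...) {
  if (inherits(healthy, "block_counts")) healthy <- list(healthy)
  if (length(healthy) < 2L) {
    stop_timmrd("need at least 2 healthy samples to fit a background prior (got %d)",
                length(healthy))
  }
  blocks <- validate_block_defs(blocks)
  # block x sample ratio matrix
  ids <- blocks$block_id
  ratio <- matrix(NA_real_, nrow = length(ids), ncol = length(healthy),
                  dimnames = list(ids, NULL))
  for (k in seq_along(healthy)) {
    d <- healthy[[k]]
    keep <- d$n_total >= min_depth & d$block_id %in% ids
    ratio[d$block_id[keep], k] <- d$n_meth[keep] / d$n_total[keep]
  }
  nuse <- rowSums(!is.na(ratio))
  if (all(nuse == 0L)) stop_timmrd("empty prior: no block has any sample at depth >= %d", min_depth)
  pooled <- mean(ratio, na.rm = TRUE)
  dots <- list(...)
  c0 <- dots$c0 %||% 100
  eps <- dots$eps %||% 0.5
  clip <- dots$clip %||% 1e-4
  fit1 <- function(i) {
    ri <- ratio[i, ]
    ri <- ri[!is.na(ri)]
    if (length(ri) < 2L) {
      m <- clip01(if (length(ri)) mean(c(ri, pooled)) else pooled, clip)
      return(list(p = m * c0 + eps, q = (1 - m) * c0 + eps,
                  fit_method = "pseudocount_fallback"))
    }
    fit_block_prior(ri, ...)
  }
  fits <- lapply(seq_along(ids), fit1)
  out <- data.frame(block_id = ids,
                    p = vapply(fits, `[[`, 0, "p"),
                    q = vapply(fits, `[[`, 0, "q"),
                    n_samples_used = as.integer(nuse),
                    fit_method = vapply(fits, `[[`, "", "fit_method"),
                    stringsAsFactors = FALSE)
  validate_background_prior(out)
}

validate_background_prior <- function(df, path = NULL) {
  check_cols(df, c("block_id", "p", "q", "n_samples_used", "fit_method"),
             "background prior", path)
  if (any(!is.finite(df$p)) || any(!is.finite(df$q)) || any(df$p <= 0) || any(df$q <= 0)) {
    stop_timmrd("background prior shapes must be strictly positive and finite")
  }
  ok <- df$fit_method %in% c("moments", "pseudocount_fallback", "known")
  if (any(!ok)) stop_timmrd("unknown fit_method '%s' in background prior", df$fit_method[!ok][1L])
  class(df) <- c("background_prior", "data.frame")
  df
}

#' Read / write a background prior table
#'
#' TSV with header `block_id, p, q, n_samples_used, fit_method`.
#'
#' @param path file path.
#' @return `read_background_prior` returns a `background_prior` data frame.
#' @export
read_background_prior <- function(path) {
  if (!file.exists(path)) stop_timmrd("prior table not found: '%s'", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_background_prior(df, path)
}

#' @param prior a `background_prior` data frame.
#' @rdname read_background_prior
#' @export
write_background_prior <- function(prior, path) {
  prior <- validate_background_prior(prior)
  utils::write.table(prior, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
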