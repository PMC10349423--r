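#' Options controlling the mixture fit and Wald scoring
#'
#' @param quad_order base number of quadrature nodes per block. The order
#'   actually used for a sample is raised to `ceiling((maxN + 1) / 2)` when
#'   depths exceed `2 * quad_order - 1`, so the block marginal is evaluated
#'   exactly (see the methods vignette); must be at least 16.
#' @param starts matrix or data frame of `(alpha, gamma)` multi-start points
#'   for the constrained optimizer.
#' @param n_polish number of best-scoring start points from which the local
#'   optimizer is run (the profiled null solution is always added).
#' @param tol convergence tolerance for the one-dimensional null profile.
#' @param percentile quantile of the chi-square(1) distribution used as the
#'   high/low classification threshold. The default 0.98 gives 5.412;
#'   0.9995 and 0.9999 are the stricter cutoffs used when higher specificity
#'   is wanted.
#' @param eps_simplex margin keeping `alpha + gamma <= 1 - eps_simplex`.
#' @param boundary_eps estimates of `alpha` at or below this are treated as
#'   the boundary and scored 0.
#' @param hess_step base step of the central-difference Hessian (shrunk near
#'   constraint boundaries).
#' @return A list of class `scoring_options`.
#' @export
scoring_options <- function(quad_order = 128L,
                            starts = as.matrix(expand.grid(alpha = c(0, 1e-3, 1e-2),
                                                           gamma = c(0, 0.05, 0.2))),
                            n_polish = 3L,
                            tol = 1e-8,
                            percentile = 0.98,
                            eps_simplex = 1e-6,
                            boundary_eps = 1e-8,
                            hess_step = 1e-4) {
  if (quad_order < 16L) stop_timmrd("quad_order must be >= 16")
  if (percentile <= 0 || percentile >= 1) stop_timmrd("percentile must lie in (0, 1)")
  starts <- as.matrix(starts)
  if (ncol(starts) != 2L) stop_timmrd("starts must have two columns (alpha, gamma)")
  structure(list(quad_order = as.integer(quad_order), starts = starts,
                 n_polish = as.integer(n_polish), tol = tol, percentile = percentile,
                 eps_simplex = eps_simplex, boundary_eps = boundary_eps,
                 hess_step = hess_step),
            class = "scoring_options")
}

#' Expected plasma methylation level of a block under the mixture
#'
#' The plasma methylation probability of a block is the convex combination
#' `alpha * beta_t + gamma * beta_n + (1 - alpha - gamma) * beta0` of the
#' patient's tumor level, adjacent-normal level and the background level,
#' weighted by the ctDNA fraction `alpha` and the normal-tissue cfDNA
#' fraction `gamma`.
#'
#' @param alpha ctDNA fraction, `>= 0`.
#' @param gamma adjacent-normal cfDNA fraction, `>= 0`; `alpha + gamma < 1`.
#' @param beta_t,beta_n,beta0 methylation fractions in `[0, 1]`.
#' @return The mixed methylation probability, in `[0, 1]`.
#' @export
mixture_mean <- function(alpha, gamma, beta_t, beta_n, beta0) {
  if (any(alpha < 0) || any(gamma < 0)) stop_timmrd("alpha and gamma must be non-negative")
  if (any(alpha + gamma >= 1)) stop_timmrd("constraint violated: alpha + gamma must be < 1")
  if (any(!is_fraction(beta_t)) || any(!is_fraction(beta_n)) || any(!is_fraction(beta0))) {
    stop_timmrd("methylation levels must lie in [0,1]")
  }
  alpha * beta_t + gamma * beta_n + (1 - alpha - gamma) * beta0
}

#' Marginal log-likelihood of one block's counts
#'
#' The marginal probability of observing `M` methylated out of `N` CpG
#' observations integrates the binomial pmf over the Beta(p, q) background
#' level transformed through the mixture. Integration is over the background
#' level directly (which carries the change-of-variables Jacobian), so the
#' marginal is a normalized pmf in `M`; at `alpha = gamma = 0` it equals the
#' closed-form beta-binomial log-pmf. Evaluated with a Gauss-Jacobi rule
#' whose weight absorbs the beta density, exact whenever
#' `N <= 2 * order - 1`.
#'
#' @inheritParams mixture_mean
#' @param N,M total and methylated CpG observations, `0 <= M <= N`.
#' @param p,q positive beta shape parameters of the background prior.
#' @param quad_order base quadrature order.
#' @return The log marginal probability; `0` when `N = 0` (a block without
#'   coverage carries no information).
#' @export
block_marginal_loglik <- function(alpha, gamma, N, M, beta_t, beta_n, p, q,
                                  quad_order = 128L) {
  if (N == 0L) return(0)
  if (M < 0L || M > N) stop_timmrd("need 0 <= M <= N")
  if (!is.finite(p) || !is.finite(q) || p <= 0 || q <= 0) {
    stop_timmrd("beta shapes must be positive and finite")
  }
  if (alpha < 0 || gamma < 0 || alpha + gamma >= 1) {
    stop_timmrd("constraint violated: need alpha >= 0, gamma >= 0, alpha + gamma < 1")
  }
  rule <- gauss_jacobi01_cached(quad_order_for(N, quad_order), p, q)
  b <- alpha * beta_t + gamma * beta_n + (1 - alpha - gamma) * rule$nodes
  lchoose(N, M) + log_sum_exp(log(rule$w) + M * log(b) + (N - M) * log1p(-b))
}

# Precomputes everything the likelihood needs for one (panel, counts, prior)
# triple: per-block counts, tissue levels, and the quadrature node/weight
# matrices. Blocks with N = 0 contribute zero log-likelihood and are dropped.
build_score_context <- function(panel, counts, prior, opts = scoring_options()) {
  if (!inherits(panel, "patient_panel")) stop_timmrd("panel must be a patient_panel")
  prior <- validate_background_prior(prior)
  miss <- setdiff(panel$block_id, prior$block_id)
  if (length(miss)) {
    stop_timmrd("panel blocks missing from the background prior: %s",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  pr <- prior[match(panel$block_id, prior$block_id), ]
  i <- match(panel$block_id, counts$block_id)
  N <- ifelse(is.na(i), 0L, counts$n_total[i])
  M <- ifelse(is.na(i), 0L, counts$n_meth[i])
  keep <- N >= 1L
  if (!any(keep)) {
    stop_timmrd("no panel block has coverage in sample '%s'",
                attr(counts, "sample_id") %||% "?")
  }
  N <- N[keep]; M <- M[keep]
  p <- pr$p[keep]; q <- pr$q[keep]
  bt <- panel$beta_t[keep]; bn <- panel$beta_n[keep]
  # group blocks by the order their depth requires, so a few deep blocks do
  # not inflate the node count of the whole panel
  ord <- vapply(N, quad_order_for, 0L, base_order = opts$quad_order)
  groups <- lapply(sort(unique(ord)), function(nu) {
    j <- which(ord == nu)
    Tn <- matrix(0, length(j), nu)
    logW <- matrix(0, length(j), nu)
    for (k in seq_along(j)) {
      rule <- gauss_jacobi01_cached(nu, p[j[k]], q[j[k]])
      Tn[k, ] <- rule$nodes
      logW[k, ] <- log(rule$w)
    }
    list(N = N[j], M = as.numeric(M[j]), NmM = as.numeric(N[j] - M[j]),
         beta_t = bt[j], beta_n = bn[j], Tn = Tn, logW = logW)
  })
  list(m = length(N), lch_total = sum(lchoose(N, M)), groups = groups,
       m_panel = nrow(panel))
}

# log-likelihood (and optionally its gradient in (alpha, gamma)) on a
# context; the inner loop over blocks and quadrature nodes is compiled
ctx_loglik <- function(ctx, alpha, gamma, grad = FALSE) {
  val <- ctx$lch_total
  ga <- gg <- 0
  for (gr in ctx$groups) {
    r <- cpp_group_loglik(gr$Tn, gr$logW, gr$M, gr$NmM, gr$beta_t, gr$beta_n,
                          alpha, gamma, grad)
    val <- val + r$value
    if (grad) {
      ga <- ga + r$grad[1L]
      gg <- gg + r$grad[2L]
    }
  }
  if (!grad) return(val)
  list(value = val, grad = c(ga, gg))
}

#' Total log-likelihood of a plasma sample under the mixture model
#'
#' Sum of block marginal log-likelihoods over the patient's selected DMBs.
#' Panel blocks absent from `counts` (or with zero depth) contribute zero.
#'
#' @inheritParams mixture_mean
#' @param panel a `patient_panel`.
#' @param counts a `block_counts` for the plasma sample.
#' @param prior a `background_prior` covering the panel blocks.
#' @param opts a [scoring_options()] list.
#' @return The total log-likelihood at `(alpha, gamma)`.
#' @export
total_loglik <- function(alpha, gamma, panel, counts, prior, opts = scoring_options()) {
  if (alpha < 0 || gamma < 0 || alpha + gamma >= 1) {
    stop_timmrd("constraint violated: need alpha >= 0, gamma >= 0, alpha + gamma < 1")
  }
  ctx <- build_score_context(panel, counts, prior, opts)
  ctx_loglik(ctx, alpha, gamma)
}

#' Fit the ctDNA / adjacent-normal mixture by constrained MLE
#'
#' Maximizes the mixed beta-binomial log-likelihood over the simplex
#' `alpha >= 0, gamma >= 0, alpha + gamma <= 1 - eps`, where `alpha` is the
#' ctDNA fraction (malignancy-density ratio) and `gamma` the adjacent-normal
#' cfDNA fraction. The optimizer is deterministic: the multi-start grid in
#' `opts$starts` is screened by log-likelihood, bound-constrained L-BFGS-B
#' with an analytic gradient is run from the best `opts$n_polish` points and
#' from the profiled null solution `(0, gamma_null)`, and the best result is
#' kept. The null log-likelihood profiles `gamma` at `alpha = 0`. The Wald
#' timMRD-score and the high/low call are filled in via [wald_score()] and
#' [classify()].
#'
#' @inheritParams total_loglik
#' @return An object of class `timmrd_fit`: a list with `alpha_hat`,
#'   `gamma_hat`, `loglik_full`, `loglik_null`, `score`, `call`
#'   (`"high"`/`"low"`), `n_blocks_used`, `converged`, `alpha_se` (NA at the
#'   boundary) and `threshold`.
#' @export
fit_timmrd <- function(panel, counts, prior, opts = scoring_options()) {
  ctx <- build_score_context(panel, counts, prior, opts)
  eps <- opts$eps_simplex

  # null model: alpha = 0, gamma profiled
  nll_null <- function(g) -ctx_loglik(ctx, 0, g)
  o <- stats::optimize(nll_null, c(0, 1 - eps), tol = max(opts$tol, 1e-6))
  cand_g <- c(o$minimum, 0)
  cand_v <- c(-o$objective, ctx_loglik(ctx, 0, 0))
  gamma_null <- cand_g[which.max(cand_v)]
  loglik_null <- max(cand_v)

  # full model on the reparameterized box u = alpha, gamma = v (1 - eps - u);
  # optim asks for the value and gradient at the same point back to back, so
  # one evaluation with gradient is cached and shared between the two calls
  memo <- list(par = NULL, val = NULL, gr = NULL)
  eval_both <- function(par) {
    if (!identical(par, memo$par)) {
      a <- par[1L]; v <- par[2L]; g <- v * (1 - eps - a)
      r <- ctx_loglik(ctx, a, g, grad = TRUE)
      memo <<- list(par = par, val = -r$value,
                    gr = -c(r$grad[1L] - v * r$grad[2L],
                            r$grad[2L] * (1 - eps - a)))
    }
    memo
  }
  negobj <- function(par) eval_both(par)$val
  neggrad <- function(par) eval_both(par)$gr
  starts <- rbind(opts$starts, c(0, gamma_null))
  starts <- starts[starts[, 1L] >= 0 & starts[, 2L] >= 0 &
                     starts[, 1L] + starts[, 2L] < 1 - eps, , drop = FALSE]
  svals <- vapply(seq_len(nrow(starts)),
                  function(i) ctx_loglik(ctx, starts[i, 1L], starts[i, 2L]), 0)
  run_idx <- unique(c(order(svals, decreasing = TRUE)[seq_len(min(opts$n_polish, nrow(starts)))],
                      nrow(starts)))  # profiled null start always polished
  best <- NULL
  for (i in run_idx) {
    a0 <- min(starts[i, 1L], 1 - eps - 1e-9)
    v0 <- min(max(starts[i, 2L] / max(1 - eps - a0, 1e-12), 0), 1)
    r <- tryCatch(
      stats::optim(c(a0, v0), negobj, neggrad, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1 - eps - 1e-12, 1),
                   control = list(maxit = 200L, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(r)) next
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best)) stop_timmrd("mixture fit failed from every start point")
  alpha_hat <- max(best$par[1L], 0)
  gamma_hat <- max(best$par[2L] * (1 - eps - alpha_hat), 0)
  loglik_full <- -best$value
  converged <- best$convergence == 0L
  if (loglik_full < loglik_null) {
    # constrained submodel cannot beat the full model; take the null solution
    alpha_hat <- 0
    gamma_hat <- gamma_null
    loglik_full <- loglik_null
    converged <- TRUE
  }

  llfun <- function(a, g) ctx_loglik(ctx, a, g)
  ws <- wald_score(llfun, alpha_hat, gamma_hat, opts)
  threshold <- classification_threshold(opts$percentile)
  structure(list(alpha_hat = alpha_hat, gamma_hat = gamma_hat,
                 loglik_full = loglik_full, loglik_null = loglik_null,
                 score = ws$score, call = classify(ws$score, threshold),
                 n_blocks_used = ctx$m, converged = converged,
                 alpha_se = ws$alpha_se, threshold = threshold,
                 percentile = opts$percentile),
            class = "timmrd_fit")
}

#' @export
print.timmrd_fit <- function(x, ...) {
  cat(sprintf("timMRD fit: alpha_hat = %.4g, gamma_hat = %.4g\n", x$alpha_hat, x$gamma_hat))
  cat(sprintf("  score = %.3f (threshold %.3f) -> timMRD-%s\n", x$score, x$threshold, x$call))
  cat(sprintf("  loglik full/null = %.3f / %.3f, blocks used = %d, converged = %s\n",
              x$loglik_full, x$loglik_null, x$n_blocks_used, x$converged))
  invisible(x)
}

#' Wald timMRD-score for the null hypothesis alpha = 0
#'
#' `score = alpha_hat^2 / var(alpha_hat)`, with the variance taken as the
#' `(alpha, alpha)` entry of the inverse observed information (negative
#' Hessian of the log-likelihood at the MLE, by central finite differences
#' with steps kept inside the constraint set). When the observed information
#' is not positive definite, the estimator falls back to the curvature of
#' the profile log-likelihood in `alpha`. Estimates at the `alpha = 0`
#' boundary score exactly 0.
#'
#' @param loglik_fn function of `(alpha, gamma)` returning the
#'   log-likelihood surface to be scored.
#' @param alpha_hat,gamma_hat the maximum-likelihood estimates.
#' @param opts a [scoring_options()] list.
#' @return List with `score` (non-negative), `alpha_se` (NA at the
#'   boundary) and `method` (`"boundary"`, `"hessian"` or `"profile"`).
#' @export
wald_score <- function(loglik_fn, alpha_hat, gamma_hat, opts = scoring_options()) {
  if (alpha_hat <= opts$boundary_eps) {
    return(list(score = 0, alpha_se = NA_real_, method = "boundary"))
  }
  eps <- opts$eps_simplex
  slack <- 1 - eps - alpha_hat - gamma_hat
  ha <- min(opts$hess_step, alpha_hat, slack / 2)
  hg <- min(opts$hess_step, gamma_hat, slack / 2)
  f0 <- loglik_fn(alpha_hat, gamma_hat)
  if (ha > 1e-10 && hg <= 1e-10) {
    # gamma_hat sits on the constraint boundary: the nuisance direction is
    # inactive, so the curvature of the alpha slice is the observed information
    faa <- (loglik_fn(alpha_hat + ha, gamma_hat) - 2 * f0 +
              loglik_fn(alpha_hat - ha, gamma_hat)) / ha^2
    if (is.finite(faa) && faa < 0) {
      v <- -1 / faa
      return(list(score = alpha_hat^2 / v, alpha_se = sqrt(v), method = "hessian"))
    }
  }
  if (ha > 1e-10 && hg > 1e-10) {
    faa <- (loglik_fn(alpha_hat + ha, gamma_hat) - 2 * f0 +
              loglik_fn(alpha_hat - ha, gamma_hat)) / ha^2
    fgg <- (loglik_fn(alpha_hat, gamma_hat + hg) - 2 * f0 +
              loglik_fn(alpha_hat, gamma_hat - hg)) / hg^2
    fag <- (loglik_fn(alpha_hat + ha, gamma_hat + hg) -
              loglik_fn(alpha_hat + ha, gamma_hat - hg) -
              loglik_fn(alpha_hat - ha, gamma_hat + hg) +
              loglik_fn(alpha_hat - ha, gamma_hat - hg)) / (4 * ha * hg)
    iaa <- -faa; igg <- -fgg; iag <- -fag
    det <- iaa * igg - iag^2
    if (is.finite(det) && det > 0 && iaa > 0) {
      v <- igg / det
      if (is.finite(v) && v > 0) {
        return(list(score = alpha_hat^2 / v, alpha_se = sqrt(v), method = "hessian"))
      }
    }
  }
  # profile-likelihood curvature in alpha (gamma re-maximized at each step)
  if (ha <= 1e-10) ha <- min(opts$hess_step, alpha_hat, (1 - eps - alpha_hat) / 2)
  lp <- function(a) {
    o <- stats::optimize(function(g) -loglik_fn(a, g), c(0, 1 - eps - a),
                         tol = max(opts$tol, 1e-6))
    max(-o$objective, loglik_fn(a, 0))
  }
  curv <- (lp(alpha_hat + ha) - 2 * lp(alpha_hat) + lp(alpha_hat - ha)) / ha^2
  if (!is.finite(curv) || curv >= 0) {
    stop_timmrd("Wald scoring failed: non-finite or non-negative profile curvature (alpha_hat = %.3g, curvature = %.3g)",
                alpha_hat, curv)
  }
  v <- -1 / curv
  list(score = alpha_hat^2 / v, alpha_se = sqrt(v), method = "profile")
}

#' Chi-square classification threshold for the timMRD-score
#'
#' The `percentile` quantile of the chi-square distribution with one degree
#' of freedom; 0.98 gives the standard cutoff 5.412.
#'
#' @param percentile a fraction in `(0, 1)`.
#' @return The threshold value.
#' @export
classification_threshold <- function(percentile = 0.98) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 1) {
    stop_timmrd("percentile must lie strictly between 0 and 1")
  }
  stats::qchisq(percentile, df = 1)
}

#' Classify a timMRD-score as high or low
#'
#' A sample is timMRD-high iff its score strictly exceeds the threshold.
#'
#' @param score non-negative Wald score.
#' @param threshold classification threshold, e.g.
#'   [classification_threshold()].
#' @return `"high"` or `"low"`.
#' @export
classify <- function(score, threshold = classification_threshold(0.98)) {
  if (any(is.na(score)) || any(score < 0)) stop_timmrd("scores must be non-negative")
  ifelse(score > threshold, "high", "low")
}

#' Exhaustive grid maximization of the mixture likelihood (test oracle)
#'
#' Evaluates the total log-likelihood on a regular `(alpha, gamma)` grid
#' over the constraint set and returns the argmax. Intended as an
#' independent check of [fit_timmrd()] on small panels; cost grows with
#' `1 / grid_step^2`.
#'
#' @inheritParams total_loglik
#' @param grid_step grid resolution in both parameters.
#' @param alpha_max,gamma_max upper limits of the searched grid.
#' @return A list of class `timmrd_grid_fit` with `alpha_hat`, `gamma_hat`
#'   and `loglik_full`.
#' @export
grid_oracle_fit <- function(panel, counts, prior, grid_step = 0.005,
                            alpha_max = NULL, gamma_max = NULL,
                            opts = scoring_options()) {
  ctx <- build_score_context(panel, counts, prior, opts)
  eps <- opts$eps_simplex
  alphas <- seq(0, min(alpha_max %||% (1 - eps), 1 - eps), by = grid_step)
  gammas <- seq(0, min(gamma_max %||% (1 - eps), 1 - eps), by = grid_step)
  best <- list(alpha_hat = 0, gamma_hat = 0, loglik_full = -Inf)
  for (g in gammas) {
    for (a in alphas) {
      if (a + g >= 1 - eps) next
      v <- ctx_loglik(ctx, a, g)
      if (v > best$loglik_full) best <- list(alpha_hat = a, gamma_hat = g, loglik_full = v)
    }
  }
  structure(c(best, list(grid_step = grid_step)), class = "timmrd_grid_fit")
}

#' Write a score table
#'
#' One row per scored sample: `sample_id, patient_id, timepoint_label,
#' alpha_hat, gamma_hat, score, call, n_blocks_used, converged`.
#'
#' @param fits named list of `timmrd_fit` objects keyed by sample id.
#' @param path output TSV path.
#' @param manifest optional manifest data frame supplying `patient_id` and
#'   `timepoint_label` per `sample_id`.
#' @export
write_score_table <- function(fits, path, manifest = NULL) {
  sid <- names(fits)
  if (is.null(sid)) stop_timmrd("fits must be a named list keyed by sample id")
  get_meta <- function(id, col) {
    if (is.null(manifest)) return(NA_character_)
    i <- match(id, manifest$sample_id)
    if (is.na(i)) NA_character_ else as.character(manifest[[col]][i])
  }
  df <- data.frame(
    sample_id = sid,
    patient_id = vapply(sid, get_meta, "", col = "patient_id"),
    timepoint_label = vapply(sid, get_meta, "", col = "timepoint_label"),
    alpha_hat = vapply(fits, `[[`, 0, "alpha_hat"),
    gamma_hat = vapply(fits, `[[`, 0, "gamma_hat"),
    score = vapply(fits, `[[`, 0, "score"),
    call = vapply(fits, `[[`, "", "call"),
    n_blocks_used = vapply(fits, `[[`, 0L, "n_blocks_used"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
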