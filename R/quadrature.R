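# Gauss-Jacobi quadrature for beta-weighted integrals on (0, 1).
#
# The block marginal likelihood integrates a binomial pmf against a
# Beta(p, q) density. Absorbing the beta density into the quadrature weight
# (Golub-Welsch on the Jacobi three-term recurrence) makes the remaining
# integrand a polynomial of degree N in the background level, so an n-node
# rule is exact whenever N <= 2n - 1 -- including shape parameters below 1,
# where the density is unbounded at the endpoints and rules with a flat
# weight converge too slowly.

# nodes t in (0,1) and normalized weights w (sum 1) such that
# sum(w * f(t)) = integral f(x) x^(p-1) (1-x)^(q-1) / B(p,q) dx
gauss_jacobi01 <- function(n, p, q) {
  stopifnot(n >= 1L, p > 0, q > 0)
  a <- q - 1; b <- p - 1; ab <- a + b
  alpha <- numeric(n)
  alpha[1L] <- (b - a) / (ab + 2)
  if (n > 1L) {
    kk <- 1:(n - 1L)
    alpha[-1L] <- (b^2 - a^2) / ((2 * kk + ab) * (2 * kk + ab + 2))
    off2 <- numeric(n - 1L)
    off2[1L] <- 4 * (a + 1) * (b + 1) / ((ab + 2)^2 * (ab + 3))
    if (n > 2L) {
      kk <- 2:(n - 1L)
      off2[kk] <- 4 * kk * (kk + a) * (kk + b) * (kk + ab) /
        ((2 * kk + ab)^2 * (2 * kk + ab + 1) * (2 * kk + ab - 1))
    }
    J <- diag(alpha)
    idx <- cbind(1:(n - 1L), 2:n)
    J[idx] <- sqrt(off2)
    J[idx[, 2:1, drop = FALSE]] <- sqrt(off2)
  } else {
    J <- matrix(alpha, 1L, 1L)
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = (e$values[ord] + 1) / 2, w = e$vectors[1L, ord]^2)
}

# memoized rules; shapes vary per block but repeat across samples and fits
.quad_cache <- new.env(parent = emptyenv())

gauss_jacobi01_cached <- function(n, p, q) {
  key <- sprintf("%d|%.10g|%.10g", n, p, q)
  rule <- .quad_cache[[key]]
  if (is.null(rule)) {
    rule <- gauss_jacobi01(n, p, q)
    .quad_cache[[key]] <- rule
  }
  rule
}

#' Clear the internal quadrature-rule cache
#'
#' Rules are memoized per (order, p, q); call this to release memory after
#' large cohort runs.
#' @export
clear_quadrature_cache <- function() {
  rm(list = ls(.quad_cache), envir = .quad_cache)
  invisible(NULL)
}

# order actually used for a block: enough nodes for polynomial exactness at
# the observed depth, rounded up to a multiple of 128 for cache reuse across
# samples, capped for cost (cap 512 is exact to depth 1023)
quad_order_for <- function(max_n, base_order, cap = 512L) {
  n <- max(base_order, ceiling((max_n + 1) / 2))
  n <- 128L * ceiling(n / 128L)
  min(as.integer(n), cap)
}
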