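# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# run expr with a local RNG state seeded at `seed`, restoring the caller's
# state afterwards; every stochastic operation in the package goes through this
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

is_fraction <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

stop_timmrd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_cols <- function(df, cols, what, path = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_timmrd("%s%s is missing column(s): %s", what,
                if (is.null(path)) "" else sprintf(" ('%s')", path),
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
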