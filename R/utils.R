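#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so deterministic simulations do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' t-based confidence interval of a mean
#'
#' @param x numeric vector.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `ci_low`, `ci_high`, `n`, `sd`.  The interval is
#'   `NA` when fewer than two observations are available.
#' @export
t_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- if (n > 0) mean(x) else NA_real_
  if (n < 2) {
    return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                n = n, sd = NA_real_))
  }
  s <- stats::sd(x)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, n = n, sd = s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
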