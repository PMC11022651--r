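# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package route their randomness through this helper so
#' that a fixed seed gives bitwise-identical output without clobbering the
#' session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return The value of `code`.
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
    set.seed(seed)
  }
  force(code)
}

stop_orbit <- function(..., class = "orbitomics_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_orbit(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Score-based interval; well behaved at very small or zero alt counts, which
#' is the operating regime of deep targeted pileups (VAF well below 0.5 at
#' depths of ~15,000x).
#'
#' @param x number of successes (vectorized).
#' @param n number of trials (vectorized).
#' @param conf confidence level, default 0.95.
#' @return A two-column matrix with columns `lower` and `upper`.
#' @examples
#' wilson_ci(300, 15000)
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  assert_that(all(n > 0), "wilson_ci: n must be positive")
  assert_that(all(x >= 0 & x <= n), "wilson_ci: x must be in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}
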