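# Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for printed percentages: one decimal place, two when
#' the magnitude is below 0.1. `round()` in R rounds half to even; published
#' land-change tables round half up, so reported numbers use this helper.
#' Applied only at reporting time, never inside computations.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Near-equality check for probability sums.
sums_to_one <- function(x, tol = 1e-9) abs(sum(x) - 1) <= tol
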