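#' Wrap angles to the half-open interval (-pi, pi]
#'
#' The canonical phase range used throughout the package. `-pi` maps to `pi`
#' (same angle, inside the interval).
#'
#' @param x numeric array of angles in radians.
#' @return array of the same shape with all values in (-pi, pi].
#' @examples
#' wrap_phase(3 * pi / 2)  # -pi/2
#' @export
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package simulations never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# DFT sample frequencies (cycles per mm), the usual fftfreq layout:
# 0, 1, ..., n/2-1, -n/2, ..., -1 all divided by n*d.
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
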