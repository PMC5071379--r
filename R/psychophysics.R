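#' Stevens power-law force transducer
#'
#' Maps physical force to perceived force magnitude through a thresholded
#' power law: perceived = `alpha * (F - F_th)^beta` for forces above the
#' detection threshold `F_th`, and 0 at or below it. Forces below the
#' threshold are imperceptible, so the perceived magnitude is zero there,
#' not negative.
#'
#' @param F physical force, N (vector allowed). Must be nonnegative.
#' @param alpha scale factor, perceived units per N^beta. Must be > 0.
#'   `alpha` cancels out of every model prediction in this package; it is
#'   kept for completeness of the transducer.
#' @param beta power-law exponent, dimensionless, > 0. Prior work on force
#'   magnitude perception with a haptic device puts it near 0.8, the
#'   package default.
#' @param F_th force detection threshold, N, >= 0.
#'
#' @return perceived force magnitude, same length as `F`.
#' @examples
#' perceived_force(0.35, alpha = 2, beta = 0.5, F_th = 0.1) # 1
#' perceived_force(c(0, 0.1, 0.2), beta = 0.8, F_th = 0.1)
#' @export
perceived_force <- function(F, alpha = 1, beta = 0.8, F_th = 0) {
  stopifnot(is.numeric(F), is.numeric(alpha), is.numeric(beta), is.numeric(F_th))
  if (any(F < 0)) abort("physical force `F` must be nonnegative")
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (beta <= 0) abort("`beta` must be > 0")
  if (F_th < 0) abort("`F_th` must be >= 0")
  ifelse(F > F_th, alpha * (F - F_th)^beta, 0)
}

#' Extrapolated field-edge position under the stiffness model
#'
#' Under the stiffness model the observer estimates the local stiffness of
#' the field as the slope of the psychophysical function at the hand
#' position and extrapolates the perceived force down to zero. With a
#' power-law transducer whose offset sits at the threshold position `x0`,
#' the scale factor and stiffness cancel and the estimated edge reduces to
#' `x - (x - x0) / beta`, independent of the physical spring constant.
#'
#' Positions are in the field-centered frame (origin at the true center,
#' positive rightward); `x` must lie in the supra-threshold region of its
#' side, i.e. at or beyond `x0` (force imperceptible between the center and
#' `x0`, so extrapolation is undefined there).
#'
#' @param x probe hand position, m (vector allowed).
#' @param x0 threshold position of the same side, m (recycled against `x`).
#' @param beta power-law exponent, > 0.
#'
#' @return estimated field-edge position, m. Equals `x0` when `x == x0` or
#'   when `beta == 1`; for `beta < 1` it undershoots `x0` toward the center
#'   and the undershoot grows linearly with probe depth.
#' @examples
#' stiffness_center_estimate(0.05, x0 = 0.0125, beta = 0.8) # 0.003125
#' stiffness_center_estimate(0.05, x0 = 0.0125, beta = 1)   # 0.0125
#' @export
stiffness_center_estimate <- function(x, x0, beta = 0.8) {
  stopifnot(is.numeric(x), is.numeric(x0), is.numeric(beta))
  if (beta <= 0) abort("`beta` must be > 0")
  n <- max(length(x), length(x0))
  x <- rep_len(x, n)
  x0 <- rep_len(x0, n)
  # same side and at least as deep as the threshold position
  sub <- sign(x) * sign(x0) < 0 | abs(x) < abs(x0) - 1e-12
  if (any(sub)) {
    abort("probe position lies in the sub-threshold region: force is imperceptible there and extrapolation is undefined")
  }
  x - (x - x0) / beta
}
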