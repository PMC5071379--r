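#' Bilateral bias under the stiffness model
#'
#' Predicted signed center error when the observer probes both sides of a
#' bilateral field, extrapolates each side's edge with
#' [stiffness_center_estimate()], and averages the two estimates. The
#' default (and only stated) probing assumption is *equal-force* probing:
#' both sides are probed where the physical force equals `probe_force`,
#' i.e. at `x = -probe_force/K_left` and `x = +probe_force/K_right`, with
#' threshold positions `x0 = -F_th/K_left` and `x0 = +F_th/K_right`.
#' Alternatively, explicit probe positions may be given.
#'
#' With `beta = 1` the extrapolation lands exactly on the threshold
#' positions and the prediction coincides with [bisection_bias()] at
#' `w = 0.5`; with `beta < 1` the bias magnitude shrinks as the probes go
#' deeper, reaching zero (and eventually reversing) for sufficiently
#' large probe forces.
#'
#' @param K_left,K_right spring stiffnesses, N/m, both > 0.
#' @param F_th force detection threshold, N.
#' @param beta power-law exponent.
#' @param probe_force force magnitude at which both sides are probed, N;
#'   must exceed `F_th`. Vectorized.
#' @param x_left,x_right explicit probe positions, m, in the
#'   field-centered frame; when supplied they override `probe_force`.
#' @return signed bias, m.
#' @examples
#' stiffness_bilateral_bias(16, 4, F_th = 0.1, beta = 0.8,
#'                          probe_force = 0.32) # +0.00421875
#' @export
stiffness_bilateral_bias <- function(K_left, K_right, F_th, beta = 0.8,
                                     probe_force = NULL,
                                     x_left = NULL, x_right = NULL) {
  if (any(K_left <= 0) || any(K_right <= 0)) {
    abort("the stiffness-model bilateral bias needs springs on both sides (K > 0)")
  }
  if (any(F_th < 0)) abort("`F_th` must be >= 0")
  x0_left <- -F_th / K_left
  x0_right <- F_th / K_right
  if (is.null(x_left) != is.null(x_right)) {
    abort("supply both `x_left` and `x_right`, or neither")
  }
  if (is.null(x_left)) {
    if (is.null(probe_force)) abort("supply `probe_force` or explicit probe positions")
    if (any(probe_force <= F_th)) {
      abort("`probe_force` must exceed the detection threshold `F_th`")
    }
    x_left <- -probe_force / K_left
    x_right <- probe_force / K_right
  }
  est_left <- stiffness_center_estimate(x_left, x0_left, beta)
  est_right <- stiffness_center_estimate(x_right, x0_right, beta)
  (est_left + est_right) / 2
}

#' Literature-threshold prediction bands for model adjudication
#'
#' For each condition, the interval of biases the bisection model predicts
#' when the force detection threshold is swept over a literature range
#' (0.05-0.1 N by default), or the envelope of stiffness-model biases over
#' a sweep of equal-force probe depths. Comparing measured biases with the
#' bisection band is the adjudication device: biases systematically below
#' the band point to the stiffness model, biases inside it to the
#' bisection model.
#'
#' The bisection band is exact: the bias is monotone in `F_th`, so the
#' band edges are the biases at the two ends of `F_th_range`. The
#' stiffness band is the range of [stiffness_bilateral_bias()] (bilateral)
#' or of the single-sided extrapolation (unilateral) over `probe_forces`;
#' shallow probes approach the bisection prediction and deep probes drive
#' the bias toward zero. By default the sweep runs from just above the
#' upper threshold down to the force at the edge of the linear field
#' region (`min(K) * x_max`).
#'
#' @param conditions a condition tibble (see [exp1_conditions()]).
#' @param model `"bisection"` or `"stiffness"`.
#' @param F_th_range numeric length-2, N; the literature threshold range.
#' @param beta power-law exponent (stiffness band only).
#' @param probe_forces optional numeric vector of probe forces, N, for the
#'   stiffness band; defaults to a per-condition sweep up to the field
#'   edge at `x_max`.
#' @param x_max half-width of the linear field region, m (default 6 cm).
#' @return `conditions` with `band_lo` and `band_hi` (m, `band_lo <=
#'   band_hi`) appended.
#' @examples
#' prediction_band(exp2_conditions())
#' @export
prediction_band <- function(conditions, model = c("bisection", "stiffness"),
                            F_th_range = c(0.05, 0.1), beta = 0.8,
                            probe_forces = NULL, x_max = 0.06) {
  model <- match.arg(model)
  check_conditions(conditions)
  if (length(F_th_range) != 2 || any(!is.finite(F_th_range)) ||
      any(F_th_range < 0)) {
    abort("`F_th_range` must be two finite nonnegative forces")
  }
  F_lo <- min(F_th_range)
  F_hi <- max(F_th_range)
  conditions <- tibble::as_tibble(conditions)
  if (model == "bisection") {
    b1 <- bisection_bias(conditions$K_left, conditions$K_right, F_lo)
    b2 <- bisection_bias(conditions$K_left, conditions$K_right, F_hi)
    return(dplyr::mutate(conditions, band_lo = pmin(b1, b2), band_hi = pmax(b1, b2)))
  }
  bands <- purrr::pmap(
    list(conditions$K_left, conditions$K_right),
    function(kl, kr) {
      K_min <- min(kl[kl > 0], kr[kr > 0])
      F_edge <- K_min * x_max
      sweep <- probe_forces %||% seq(F_hi * 1.0001, F_edge, length.out = 64)
      sweep <- sweep[sweep > F_hi]
      if (length(sweep) == 0) abort("empty probe sweep for the stiffness band")
      if (kl > 0 && kr > 0) {
        b <- stiffness_bilateral_bias(kl, kr, F_th = F_hi, beta = beta,
                                      probe_force = sweep)
      } else {
        s <- if (kr > 0) 1 else -1
        K <- max(kl, kr)
        b <- s * stiffness_center_estimate(sweep / K, F_hi / K, beta)
      }
      # envelope from the bisection band edge down toward zero
      range(c(b, 0))
    }
  )
  dplyr::mutate(conditions,
                band_lo = purrr::map_dbl(bands, 1),
                band_hi = purrr::map_dbl(bands, 2))
}
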