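#' Bisection-model parameter set
#'
#' Bundles the free parameters of the bisection model: the force detection
#' threshold, its trial-to-trial variability, and the positional noise of
#' the hand-position sense. The bilateral experiment carries two positional
#' noise values (visual feedback of hand position present vs absent); the
#' unilateral experiment carries a single one. The left/right weight `w`
#' exists in the model but is fixed at 1/2 here, appropriate for a device
#' centered on the body midline.
#'
#' All values are SI: newtons and meters.
#'
#' @param F_th force detection threshold, N, >= 0.
#' @param sigma_F SD of the force threshold across trials, N, >= 0.
#' @param sigma_P_fp positional noise SD with visual feedback present, m.
#' @param sigma_P_fa positional noise SD with visual feedback absent, m.
#' @param sigma_P positional noise SD for the unilateral experiment, m.
#' @param w weight of the right-side threshold position, in `[0, 1]`.
#'
#' @return An object of class `bisection_params` (a named list).
#' @examples
#' bisection_params(F_th = 0.085, sigma_F = 0.052,
#'                  sigma_P_fp = 0.0093, sigma_P_fa = 0.012)
#' @export
bisection_params <- function(F_th, sigma_F = 0, sigma_P_fp = NA_real_,
                             sigma_P_fa = NA_real_, sigma_P = NA_real_,
                             w = 0.5) {
  if (F_th < 0) abort("`F_th` must be >= 0")
  if (sigma_F < 0) abort("`sigma_F` must be >= 0")
  for (s in c(sigma_P_fp, sigma_P_fa, sigma_P)) {
    if (!is.na(s) && s < 0) abort("positional noise SDs must be >= 0")
  }
  if (w < 0 || w > 1) abort("`w` must lie in [0, 1]")
  structure(
    list(F_th = F_th, sigma_F = sigma_F, sigma_P_fp = sigma_P_fp,
         sigma_P_fa = sigma_P_fa, sigma_P = sigma_P, w = w),
    class = "bisection_params"
  )
}

#' @export
print.bisection_params <- function(x, ...) {
  cat("<bisection_params>\n")
  cat(sprintf("  F_th    = %.4g N   sigma_F = %.4g N\n", x$F_th, x$sigma_F))
  cat(sprintf("  sigma_P = %.4g m (fp) / %.4g m (fa) / %.4g m (uni)\n",
              x$sigma_P_fp, x$sigma_P_fa, x$sigma_P))
  cat(sprintf("  w       = %.3g\n", x$w))
  invisible(x)
}

#' Default generative parameters for the synthetic experiments
#'
#' Parameter sets used by the synthetic-experiment generator to emulate
#' typical human performance with weak elastic force fields: a detection
#' threshold of 0.085 N (bilateral task) or 0.12 N (unilateral task) with
#' threshold noise of about 0.05-0.06 N, and positional noise of roughly
#' 1 cm that shrinks when visual feedback of hand position is available
#' (0.93 cm vs 1.2 cm) and is smallest in the unilateral task (0.51 cm).
#'
#' @param experiment `"exp1"` (bilateral) or `"exp2"` (unilateral).
#' @return A [bisection_params()] object.
#' @export
default_bisection_params <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    bisection_params(F_th = 0.085, sigma_F = 0.052,
                     sigma_P_fp = 0.0093, sigma_P_fa = 0.012)
  } else {
    bisection_params(F_th = 0.12, sigma_F = 0.062, sigma_P = 0.0051)
  }
}

#' Bisection-model bias
#'
#' Predicted signed error of the perceived field center under the
#' bisection model, in the field-centered frame (positive rightward).
#' For a bilateral field the perceived center is the `w`-weighted mean of
#' the two threshold positions `-F_th/K_left` and `+F_th/K_right`; for a
#' unilateral field it sits at the single threshold position, so the bias
#' is `F_th/K` directed toward the spring (positive for a right-side
#' spring, negative for a left-side one).
#'
#' @param K_left,K_right spring stiffness, N/m; 0 where no spring is
#'   present (vectorized; recycled to a common length).
#' @param F_th force detection threshold, N.
#' @param w weight of the right-side threshold position (bilateral only).
#' @return signed bias, m.
#' @examples
#' bisection_bias(16, 4, F_th = 0.1)      # +0.009375 toward the weak spring
#' bisection_bias(8, 8, F_th = 0.085)     # 0: symmetric field
#' bisection_bias(0, 8, F_th = 0.12)      # +0.015: unilateral, right spring
#' @export
bisection_bias <- function(K_left, K_right, F_th, w = 0.5) {
  n <- max(length(K_left), length(K_right), length(F_th))
  K_left <- rep_len(K_left, n)
  K_right <- rep_len(K_right, n)
  F_th <- rep_len(F_th, n)
  if (any(K_left < 0 | K_right < 0)) abort("stiffnesses must be >= 0")
  if (any(K_left == 0 & K_right == 0)) abort("at least one spring must have K > 0")
  if (any(F_th < 0)) abort("`F_th` must be >= 0")
  dplyr::case_when(
    K_left > 0 & K_right > 0 ~ (1 - w) * (-F_th / ifelse(K_left > 0, K_left, NA_real_)) +
      w * (F_th / ifelse(K_right > 0, K_right, NA_real_)),
    K_right > 0 ~ F_th / K_right,   # spring on the right: bias rightward
    TRUE ~ -F_th / K_left           # spring on the left: bias leftward
  )
}

#' Bisection-model response variability
#'
#' Predicted within-participant SD of the endpoint under the bisection
#' model. Threshold noise propagates through each spring as
#' `sigma_F / K`, positional noise enters once per threshold position,
#' and the two sides combine with weights `(1-w)` and `w` (variances add,
#' assuming independent noise on the two sides). For a unilateral field
#' the SD is `sqrt(sigma_F^2 / K^2 + sigma_P^2)`.
#'
#' @inheritParams bisection_bias
#' @param sigma_F SD of the force threshold, N.
#' @param sigma_P positional noise SD, m (the caller chooses the
#'   feedback-appropriate value).
#' @return SD of the endpoint, m (nonnegative).
#' @examples
#' bisection_sd(8, 8, sigma_F = 0.052, sigma_P = 0.0093)   # ~0.008023
#' bisection_sd(0, 8, sigma_F = 0.062, sigma_P = 0.0051)   # ~0.009297
#' @export
bisection_sd <- function(K_left, K_right, sigma_F, sigma_P, w = 0.5) {
  n <- max(length(K_left), length(K_right), length(sigma_F), length(sigma_P))
  K_left <- rep_len(K_left, n)
  K_right <- rep_len(K_right, n)
  sigma_F <- rep_len(sigma_F, n)
  sigma_P <- rep_len(sigma_P, n)
  if (any(sigma_F < 0) || any(sigma_P < 0)) abort("noise SDs must be >= 0")
  if (any(K_left == 0 & K_right == 0)) abort("at least one spring must have K > 0")
  bilateral <- K_left > 0 & K_right > 0
  needs_left <- bilateral & (1 - w) > 0
  needs_right <- bilateral & w > 0
  # a side whose variance term is weighted needs a finite sigma_F/K
  if (any((needs_left & K_left == 0) | (needs_right & K_right == 0))) {
    abort("zero stiffness on a side whose variance term is used")
  }
  var_bi <- (1 - w)^2 * (sigma_F^2 / ifelse(K_left > 0, K_left^2, Inf) + sigma_P^2) +
    w^2 * (sigma_F^2 / ifelse(K_right > 0, K_right^2, Inf) + sigma_P^2)
  K_uni <- ifelse(K_right > 0, K_right, K_left)
  var_uni <- sigma_F^2 / K_uni^2 + sigma_P^2
  sqrt(ifelse(bilateral, var_bi, var_uni))
}

# Pick the positional-noise SD matching each condition's feedback label.
sigma_P_for <- function(params, feedback) {
  out <- dplyr::case_when(
    feedback == "present" ~ params$sigma_P_fp,
    feedback == "absent" ~ params$sigma_P_fa,
    TRUE ~ params$sigma_P
  )
  if (any(is.na(out))) {
    abort("`params` lacks the positional-noise SD required by a condition's feedback label")
  }
  out
}

#' Per-condition bisection-model predictions
#'
#' Evaluates the bisection model's bias and SD for every row of a
#' condition table, picking the feedback-appropriate positional noise.
#'
#' @param conditions a condition tibble as returned by [exp1_conditions()]
#'   or [exp2_conditions()] (columns `K_left`, `K_right`, `side`,
#'   `feedback`).
#' @param params a [bisection_params()] object.
#' @return `conditions` with columns `mu_x` (bias, m) and `sigma_x`
#'   (SD, m) appended.
#' @examples
#' bisection_predict(exp2_conditions(), default_bisection_params("exp2"))
#' @export
bisection_predict <- function(conditions, params) {
  check_conditions(conditions)
  stopifnot(inherits(params, "bisection_params"))
  sP <- sigma_P_for(params, conditions$feedback)
  dplyr::mutate(
    tibble::as_tibble(conditions),
    mu_x = bisection_bias(.data$K_left, .data$K_right, params$F_th, params$w),
    sigma_x = bisection_sd(.data$K_left, .data$K_right, params$sigma_F, sP, params$w)
  )
}
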