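#' Rendered force of a linear elastic field
#'
#' Force along the movement axis at hand position `x` (workspace frame)
#' for a field centered at `center`. Bilateral fields are repulsive: the
#' left spring pushes leftward (`F = K_left * (x - center) < 0` left of
#' the center) and the right spring pushes rightward. Unilateral fields
#' are attractive, rendered as the edge of a virtual object: inside the
#' object the spring pushes the hand back out toward the edge, outside it
#' the force is zero.
#'
#' @param x hand position, m, workspace frame (vectorized).
#' @param center field center, m.
#' @param K_left,K_right spring stiffnesses, N/m (0 where absent).
#' @return force, N, positive rightward.
#' @export
field_force <- function(x, center, K_left, K_right) {
  d <- x - center
  bilateral <- K_left > 0 && K_right > 0
  if (bilateral) {
    ifelse(d < 0, K_left * d, K_right * d)
  } else if (K_right > 0) {
    ifelse(d > 0, -K_right * d, 0)
  } else if (K_left > 0) {
    ifelse(d < 0, -K_left * d, 0)
  } else {
    abort("at least one spring must have K > 0")
  }
}

# Deterministic substream seeds derived from one dataset-level seed, so
# design randomization and endpoint noise are independent streams.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% .Machine$integer.max)
}

#' Simulate trial endpoints from a generative model
#'
#' Draws one response endpoint per trial of a design:
#' `endpoint = center + bias + Normal(0, sd)`, where bias and SD come
#' from the chosen generative model. The `"bisection"` generator uses
#' [bisection_bias()] and [bisection_sd()]. The `"stiffness"` generator
#' places the mean at the equal-force-probe extrapolation
#' ([stiffness_bilateral_bias()], or its single-sided analogue for
#' unilateral fields) and uses the positional noise alone as the endpoint
#' SD (the extrapolated estimate inherits the hand-position sense's
#' noise; no threshold-noise term applies because the threshold position
#' is not what is being reported).
#'
#' @param design a design tibble from [generate_design()].
#' @param params a [bisection_params()] object.
#' @param generator `"bisection"` or `"stiffness"`.
#' @param seed integer seed for the endpoint noise stream.
#' @param beta power-law exponent (stiffness generator).
#' @param probe_force probe force for the stiffness generator, N; default
#'   is the per-condition field-edge force `min(K) * 0.06`.
#' @return `design` with columns `mu_x`, `sigma_x` (model bias and SD, m)
#'   and `endpoint_m` (workspace frame) appended.
#' @export
simulate_endpoints <- function(design, params,
                               generator = c("bisection", "stiffness"),
                               seed, beta = 0.8, probe_force = NULL) {
  generator <- match.arg(generator)
  check_conditions(design)
  stopifnot(inherits(params, "bisection_params"))
  withr::local_seed(as.integer(seed))
  sP <- sigma_P_for(params, design$feedback)
  if (generator == "bisection") {
    mu <- bisection_bias(design$K_left, design$K_right, params$F_th, params$w)
    sig <- bisection_sd(design$K_left, design$K_right, params$sigma_F, sP, params$w)
  } else {
    mu <- purrr::pmap_dbl(
      list(design$K_left, design$K_right),
      function(kl, kr) {
        pf <- probe_force %||% (min(kl[kl > 0], kr[kr > 0]) * 0.06)
        if (kl > 0 && kr > 0) {
          stiffness_bilateral_bias(kl, kr, params$F_th, beta, probe_force = pf)
        } else {
          s <- if (kr > 0) 1 else -1
          K <- max(kl, kr)
          s * stiffness_center_estimate(pf / K, params$F_th / K, beta)
        }
      }
    )
    sig <- sP
  }
  dplyr::mutate(tibble::as_tibble(design),
                mu_x = mu, sigma_x = sig,
                endpoint_m = .data$center_m + mu + rnorm(dplyr::n(), 0, sig))
}

#' Exploration profile for simulated trajectories
#'
#' Trajectory statistics of simulated exploration, chosen to match
#' typical behavior in the two tasks: participants sweep back and forth
#' across the field in roughly sinusoidal movements whose amplitude
#' decays as they home in on the perceived center. Defaults: about 10.9 s
#' per trial with about 11 direction changes in the bilateral task, and
#' 8.5 s with about 8 direction changes in the unilateral task.
#'
#' @param experiment `"exp1"` or `"exp2"` (sets the defaults).
#' @param duration_s total trial duration, s.
#' @param n_direction_changes approximate number of movement-direction
#'   reversals over the trial.
#' @param amp_min_m minimum initial exploration amplitude, m; guarantees
#'   that bilateral trajectories sweep across the field center.
#' @param hold_s duration of the final settle at the endpoint, s; must be
#'   at least the 0.1 s endpoint-averaging window.
#' @param sample_rate_hz recording rate, Hz.
#' @return a list of class `exploration_profile`.
#' @export
exploration_profile <- function(experiment = c("exp1", "exp2"),
                                duration_s = NULL,
                                n_direction_changes = NULL,
                                amp_min_m = 0.04, hold_s = 0.25,
                                sample_rate_hz = 250) {
  experiment <- match.arg(experiment)
  duration_s <- duration_s %||% if (experiment == "exp1") 10.9 else 8.5
  n_direction_changes <- n_direction_changes %||%
    if (experiment == "exp1") 11.1 else 8.2
  if (duration_s <= 0) abort("`duration_s` must be positive")
  if (hold_s < 0.1) abort("`hold_s` must cover the 0.1 s endpoint window")
  if (duration_s <= hold_s) abort("`duration_s` must exceed `hold_s`")
  structure(list(duration_s = duration_s,
                 n_direction_changes = n_direction_changes,
                 amp_min_m = amp_min_m, hold_s = hold_s,
                 sample_rate_hz = sample_rate_hz),
            class = "exploration_profile")
}

#' Simulate a full trial record (trajectory + force samples)
#'
#' Expands endpoint-level simulations into per-sample records: a damped
#' sinusoidal exploration around the endpoint starting at the trial's
#' start position, settling so that the hand rests exactly at the
#' endpoint for the final `hold_s` seconds, sampled at 250 Hz. The force
#' channel follows the field law ([field_force()]) at each position; the
#' quality flag is `FALSE` everywhere (use [flag_epoch()] to inject
#' rejection-trigger epochs).
#'
#' @param endpoints output of [simulate_endpoints()] (design columns plus
#'   `endpoint_m`).
#' @param profile an [exploration_profile()]; defaults to the profile of
#'   the design's experiment.
#' @return A tibble of samples: `trial`, `t` (s), `x_m`, `force_N`,
#'   `quality_flag`.
#' @export
simulate_trajectory <- function(endpoints, profile = NULL) {
  stopifnot(all(c("trial", "center_m", "start_m", "endpoint_m") %in% names(endpoints)))
  profile <- profile %||% exploration_profile(endpoints$experiment[1])
  stopifnot(inherits(profile, "exploration_profile"))
  dt <- 1 / profile$sample_rate_hz
  t_all <- seq(0, profile$duration_s, by = dt)
  t_osc <- profile$duration_s - profile$hold_s
  freq <- profile$n_direction_changes / (2 * t_osc)
  purrr::map_dfr(seq_len(nrow(endpoints)), function(i) {
    tr <- endpoints[i, ]
    e <- tr$endpoint_m
    A0 <- max(abs(tr$start_m - e), profile$amp_min_m)
    # full-amplitude sweeps for the first third of the exploration, then
    # exponential zooming-in; the hand settles on the endpoint for the
    # final hold so the last 100 ms average IS the endpoint
    t_p <- 0.3 * t_osc
    lambda <- log(A0 / 1e-4) / (t_osc - t_p)
    amp <- A0 * exp(-lambda * pmax(t_all - t_p, 0))
    phi <- asin((tr$start_m - e) / A0)
    x <- e + amp * sin(2 * pi * freq * t_all + phi)
    x[t_all >= t_osc] <- e
    tibble::tibble(
      trial = tr$trial,
      t = t_all,
      x_m = x,
      force_N = field_force(x, tr$center_m, tr$K_left, tr$K_right),
      quality_flag = FALSE
    )
  })
}

#' Inject a flagged (high-frequency-noise) epoch into trial records
#'
#' Marks `quality_flag = TRUE` for samples of one trial falling in
#' `[from_s, from_s + duration_s)`, emulating the device's
#' high-frequency-noise episodes that trigger trial rejection when they
#' last more than 0.5 s.
#'
#' @param samples a sample tibble from [simulate_trajectory()].
#' @param trial trial id to flag.
#' @param from_s epoch start, s.
#' @param duration_s epoch duration, s.
#' @return `samples` with the epoch flagged.
#' @export
flag_epoch <- function(samples, trial, from_s, duration_s) {
  if (duration_s <= 0) abort("`duration_s` must be positive")
  hit <- samples$trial == trial & samples$t >= from_s &
    samples$t < from_s + duration_s
  samples$quality_flag[hit] <- TRUE
  samples
}

#' Simulate a cohort of participants (endpoint level)
#'
#' Generates an independent randomized design and endpoint draws for each
#' of `n_participants` participants. Each participant gets its own
#' deterministic substream of `seed` (one stream for the design, one for
#' the endpoint noise), so cohorts are reproducible and designs are
#' identical across generative models at the same seed.
#'
#' @inheritParams simulate_endpoints
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_participants cohort size (the emulated studies used 12).
#' @return A tibble of all participants' trials with a `participant`
#'   column prepended.
#' @export
simulate_cohort <- function(experiment = c("exp1", "exp2"),
                            n_participants = 12, params = NULL,
                            generator = c("bisection", "stiffness"),
                            seed = 1, beta = 0.8, probe_force = NULL) {
  experiment <- match.arg(experiment)
  generator <- match.arg(generator)
  params <- params %||% default_bisection_params(experiment)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    design <- generate_design(experiment, seed = substream(seed, 2 * p))
    sims <- simulate_endpoints(design, params, generator,
                               seed = substream(seed, 2 * p + 1),
                               beta = beta, probe_force = probe_force)
    dplyr::mutate(sims, participant = p, .before = 1)
  })
}
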