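#' Response endpoint of a trial
#'
#' The endpoint is the mean hand position over the final 100 ms of the
#' trial (25 samples at 250 Hz), the position the participant was holding
#' when confirming the response.
#'
#' @param t sample times, s (ascending).
#' @param x hand positions, m.
#' @param window_s averaging window, s.
#' @return endpoint, m.
#' @export
extract_endpoint <- function(t, x, window_s = 0.1) {
  stopifnot(length(t) == length(x), length(t) > 1)
  if (diff(range(t)) < window_s - 1e-9) {
    abort("trial record shorter than the endpoint-averaging window")
  }
  mean(x[t > max(t) - window_s + 1e-12])
}

#' @describeIn extract_endpoint per-trial endpoints for a sample tibble
#'   (columns `trial`, `t`, `x_m`); returns a tibble `trial`,
#'   `endpoint_m`.
#' @param samples a tibble of samples (`trial`, `t`, `x_m`).
#' @export
extract_endpoints <- function(samples, window_s = 0.1) {
  samples |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(endpoint_m = extract_endpoint(.data$t, .data$x_m, window_s),
                     .groups = "drop")
}

#' Zero-crossings of the measured force
#'
#' Positions at which the force signal changes direction during
#' exploration, located by linear interpolation between adjacent samples.
#' In a bilateral field these crossings mark the rendered field center;
#' their per-trial mean is the best available estimate of the center the
#' participant actually experienced.
#'
#' @param x hand positions, m.
#' @param force forces, N.
#' @return positions of the sign changes, m (possibly empty).
#' @examples
#' zero_crossings(c(0.009, 0.011), c(-0.01, 0.01)) # 0.010
#' @export
zero_crossings <- function(x, force) {
  stopifnot(length(x) == length(force), length(x) > 1)
  f1 <- head(force, -1)
  f2 <- tail(force, -1)
  x1 <- head(x, -1)
  x2 <- tail(x, -1)
  i <- which(f1 * f2 < 0)
  cross <- x1[i] - f1[i] * (x2[i] - x1[i]) / (f2[i] - f1[i])
  # samples landing exactly on zero between opposite-signed neighbours
  j <- which(force == 0)
  j <- j[j > 1 & j < length(force)]
  j <- j[force[j - 1] * force[j + 1] < 0]
  sort(c(cross, x[j]))
}

#' Per-trial field-center estimate for bilateral trials
#'
#' Mean of the force zero-crossings of one trial. Only defined for
#' bilateral fields: in a unilateral field the force is zero everywhere
#' outside the object, so zero-crossings are not meaningful and the
#' designed center is used downstream instead.
#'
#' @inheritParams zero_crossings
#' @param bilateral is the trial's field bilateral?
#' @return center estimate, m.
#' @export
estimate_center_exp1 <- function(x, force, bilateral = TRUE) {
  if (!bilateral) {
    abort("zero-crossing center estimation is defined for bilateral fields only")
  }
  zc <- zero_crossings(x, force)
  if (length(zc) == 0) {
    abort("no force zero-crossing found; cannot estimate the field center")
  }
  mean(zc)
}

# Longest run of quality_flag == TRUE, in seconds (n_samples / rate).
max_flag_run_s <- function(t, quality_flag) {
  if (!any(quality_flag)) return(0)
  dt <- stats::median(diff(t))
  r <- rle(quality_flag)
  max(r$lengths[r$values]) * dt
}

#' Build a per-trial error table from sample records
#'
#' Joins sample records with their designs and computes, per trial, the
#' endpoint, the center reference and the signed error. Bilateral trials
#' are referenced to the per-trial mean force zero-crossing (the
#' empirical center); unilateral trials to the designed center. The
#' longest flagged (high-frequency-noise) run is carried along for the
#' outlier filter.
#'
#' @param samples sample tibble (`trial`, `t`, `x_m`, `force_N`,
#'   `quality_flag`).
#' @param design design tibble from [generate_design()] (may carry extra
#'   columns, e.g. `participant`).
#' @return one row per trial: the design columns plus `endpoint_m`,
#'   `center_ref_m`, `error_m`, `max_flag_run_s`.
#' @export
preprocess_trials <- function(samples, design) {
  stopifnot(all(c("trial", "t", "x_m", "force_N", "quality_flag") %in% names(samples)))
  per_trial <- samples |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      endpoint_m = extract_endpoint(.data$t, .data$x_m),
      zc_mean = {
        zc <- zero_crossings(.data$x_m, .data$force_N)
        if (length(zc)) mean(zc) else NA_real_
      },
      max_flag_run_s = max_flag_run_s(.data$t, .data$quality_flag),
      .groups = "drop"
    )
  out <- dplyr::inner_join(tibble::as_tibble(design), per_trial, by = "trial")
  if (nrow(out) != nrow(per_trial)) {
    abort("sample records and design table do not cover the same trials")
  }
  bilateral <- out$side == "bilateral"
  if (any(bilateral & is.na(out$zc_mean))) {
    abort("a bilateral trial has no force zero-crossing; cannot reference its error")
  }
  out |>
    dplyr::mutate(center_ref_m = ifelse(bilateral, .data$zc_mean, .data$center_m),
                  error_m = .data$endpoint_m - .data$center_ref_m) |>
    dplyr::select(-"zc_mean")
}

#' Endpoint-level trials without trajectories
#'
#' Turns endpoint simulations ([simulate_endpoints()] /
#' [simulate_cohort()]) directly into the per-trial error table consumed
#' by the outlier filter and summaries, referencing errors to the
#' designed center (exact for simulations, where the rendered and
#' designed centers coincide).
#'
#' @param endpoints tibble with design columns and `endpoint_m`.
#' @return the endpoint tibble with `center_ref_m`, `error_m` and a zero
#'   `max_flag_run_s` appended.
#' @export
trials_from_endpoints <- function(endpoints) {
  stopifnot(all(c("endpoint_m", "center_m") %in% names(endpoints)))
  dplyr::mutate(tibble::as_tibble(endpoints),
                center_ref_m = .data$center_m,
                error_m = .data$endpoint_m - .data$center_m,
                max_flag_run_s = 0)
}

#' Two-criterion outlier rejection
#'
#' Criterion 1 rejects trials whose flagged high-frequency-noise episode
#' lasted more than 0.5 s consecutively (a run of exactly 0.5 s is
#' kept). Criterion 2 is a single leave-one-out pass over the endpoint
#' errors within each condition (and participant, when present): trial i
#' is rejected iff its error lies more than 5 SD from the mean of the
#' condition, both computed without trial i. If the remaining trials are
#' all identical (leave-one-out SD of 0), any trial deviating from them
#' is rejected. Criterion 2 needs at least 3 trials in the condition and
#' is applied once, to the trials surviving criterion 1 — it is not
#' iterated.
#'
#' @param trials per-trial tibble from [preprocess_trials()] or
#'   [trials_from_endpoints()].
#' @param n_sd rejection radius of criterion 2, in leave-one-out SDs.
#' @param max_flag_s criterion-1 run-length limit, s.
#' @return `trials` with `kept` (logical) and `reject_reason`
#'   (`NA`, `"flag_run"`, `"deviant"`) appended.
#' @export
reject_outliers <- function(trials, n_sd = 5, max_flag_s = 0.5) {
  trials <- tibble::as_tibble(trials)
  stopifnot("error_m" %in% names(trials))
  flag <- if ("max_flag_run_s" %in% names(trials)) {
    trials$max_flag_run_s > max_flag_s + 1e-9
  } else {
    rep(FALSE, nrow(trials))
  }
  keys <- intersect(c("participant", "condition_id"), names(trials))
  if (length(keys) == 0) abort("`trials` needs a `condition_id` column")
  deviant <- rep(FALSE, nrow(trials))
  split_idx <- split(seq_len(nrow(trials)), trials[keys], drop = TRUE)
  for (idx in split_idx) {
    idx <- idx[!flag[idx]]
    if (length(idx) < 3) next
    err <- trials$error_m[idx]
    for (k in seq_along(idx)) {
      rest <- err[-k]
      dev <- abs(err[k] - mean(rest))
      s <- sd(rest)
      deviant[idx[k]] <- if (s == 0) dev > 0 else dev > n_sd * s
    }
  }
  dplyr::mutate(trials,
                kept = !flag & !deviant,
                reject_reason = dplyr::case_when(flag ~ "flag_run",
                                                 deviant ~ "deviant",
                                                 TRUE ~ NA_character_))
}

#' Per-condition and group-level summaries
#'
#' `summarize_conditions()` collapses kept trials to one row per
#' (participant x) condition: the bias (mean signed error) and the SD of
#' the errors across trials (sample SD, n-1 denominator).
#' `summarize_group()` then averages across participants: the group bias
#' is the unweighted mean of the per-participant biases (with its
#' standard error) and the group SD is the mean per-participant SD —
#' the form in which the data enter the model fit.
#'
#' @param trials per-trial tibble with `kept` from [reject_outliers()]
#'   (trials without a `kept` column are all treated as kept).
#' @return `summarize_conditions()`: one row per participant x condition
#'   with `bias_m`, `sd_m`, `n_trials`, `n_rejected`.
#' @export
summarize_conditions <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if (!"kept" %in% names(trials)) trials$kept <- TRUE
  keys <- intersect(
    c("participant", "condition_id", "experiment", "K_left", "K_right",
      "side", "feedback"),
    names(trials)
  )
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      bias_m = mean(.data$error_m[.data$kept]),
      sd_m = sd(.data$error_m[.data$kept]),
      n_trials = sum(.data$kept),
      n_rejected = sum(!.data$kept),
      .groups = "drop"
    )
  if (any(out$n_trials < 2)) {
    abort("a condition has fewer than 2 kept trials; bias/SD are undefined")
  }
  out
}

#' @describeIn summarize_conditions average condition summaries across
#'   participants; returns one row per condition with `bias_m`,
#'   `se_bias_m`, `sd_m`, `n_participants`.
#' @param condition_summaries output of [summarize_conditions()].
#' @export
summarize_group <- function(condition_summaries) {
  keys <- intersect(
    c("condition_id", "experiment", "K_left", "K_right", "side", "feedback"),
    names(condition_summaries)
  )
  condition_summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      se_bias_m = sd(.data$bias_m) / sqrt(dplyr::n()),
      sd_m = mean(.data$sd_m),
      bias_m = mean(.data$bias_m),
      .groups = "drop"
    ) |>
    dplyr::relocate("bias_m", "se_bias_m", "sd_m", .after = dplyr::last_col())
}
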