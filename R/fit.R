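#' Joint bias-and-variability least-squares objective
#'
#' The fitting objective of the bisection model: the sum over conditions
#' of the squared bias residual plus the squared SD residual,
#' `SS = sum_i (x_i - mu_i)^2 + (s_i - sigma_i)^2`, with every term in
#' meters so both parts live in the same unit (m^2). Bias and
#' variability are deliberately fitted together: the threshold `F_th`
#' only enters the biases while the noise parameters only enter the SDs,
#' so the joint objective identifies all of them at once.
#'
#' @param summaries a group-summary tibble ([summarize_group()]) with
#'   condition columns and `bias_m`, `sd_m`.
#' @param params a [bisection_params()] object.
#' @return the objective value, m^2.
#' @export
bisection_loss <- function(summaries, params) {
  stopifnot(all(c("bias_m", "sd_m") %in% names(summaries)))
  pred <- bisection_predict(summaries, params)
  sum((summaries$bias_m - pred$mu_x)^2 + (summaries$sd_m - pred$sigma_x)^2)
}

# Parameter vector <-> bisection_params, per experiment.
theta_names <- function(experiment) {
  if (experiment == "exp1") c("F_th", "sigma_F", "sigma_P_fp", "sigma_P_fa")
  else c("F_th", "sigma_F", "sigma_P")
}

theta_to_params <- function(theta, experiment, w = 0.5) {
  th <- as.list(setNames(theta, theta_names(experiment)))
  if (experiment == "exp1") {
    bisection_params(th$F_th, th$sigma_F, sigma_P_fp = th$sigma_P_fp,
                     sigma_P_fa = th$sigma_P_fa, w = w)
  } else {
    bisection_params(th$F_th, th$sigma_F, sigma_P = th$sigma_P, w = w)
  }
}

# Deterministic multi-start grid: thresholds spanning 0.01-0.3 N, noise
# SDs spanning 0-3 cm (position) and 0.01-0.15 N (force threshold).
start_grid <- function(experiment) {
  F_th <- c(0.01, 0.1, 0.3)
  sigma_F <- c(0.01, 0.15)
  sigma_P <- c(0.002, 0.03)
  g <- if (experiment == "exp1") {
    expand.grid(F_th = F_th, sigma_F = sigma_F,
                sigma_P_fp = sigma_P, sigma_P_fa = sigma_P)
  } else {
    expand.grid(F_th = F_th, sigma_F = sigma_F, sigma_P = sigma_P)
  }
  as.matrix(g)
}

#' Fit the bisection model to group summaries
#'
#' Minimizes [bisection_loss()] over the model's nonnegative parameters:
#' for the bilateral experiment `(F_th, sigma_F, sigma_P_fp,
#' sigma_P_fa)` jointly over both feedback conditions (14 bias + 14 SD
#' data points, 4 free parameters), for the unilateral experiment
#' `(F_th, sigma_F, sigma_P)` (6 + 6 points, 3 parameters). The weight
#' `w` stays fixed at 0.5. Optimization is a deterministic multi-start:
#' bounded quasi-Newton (`nlminb`, lower bound 0) from a fixed grid of
#' starting points; ties between starts (SS within 1e-12) are broken by
#' the lowest fitted `F_th`.
#'
#' @param summaries group-summary tibble with `bias_m` and `sd_m` in
#'   meters (see [summarize_group()]; any table with the condition
#'   columns works).
#' @param experiment `"exp1"` or `"exp2"`; inferred from the summaries
#'   when omitted.
#' @param w fixed right-side weight.
#' @param starts optional matrix of starting points (columns named as
#'   the parameter vector) overriding the default grid.
#' @return An object of class `bisect_fit`: fitted [bisection_params()],
#'   the objective value `ss` (m^2), goodness of fit `r2`, `n_points`,
#'   `converged`, `starts_tried`, and the per-condition predictions.
#' @examples
#' truth <- default_bisection_params("exp2")
#' dat <- bisection_predict(exp2_conditions(), truth) |>
#'   dplyr::rename(bias_m = mu_x, sd_m = sigma_x)
#' fit <- fit_bisection(dat)
#' tidy(fit)
#' @export
fit_bisection <- function(summaries, experiment = NULL, w = 0.5,
                          starts = NULL) {
  summaries <- tibble::as_tibble(summaries)
  check_conditions(summaries)
  stopifnot(all(c("bias_m", "sd_m") %in% names(summaries)))
  experiment <- experiment %||% unique(summaries$experiment)
  if (length(experiment) != 1 || !experiment %in% c("exp1", "exp2")) {
    abort("`summaries` must belong to a single experiment (\"exp1\" or \"exp2\")")
  }
  if (experiment == "exp1" &&
      !all(c("present", "absent") %in% summaries$feedback)) {
    abort("the bilateral fit needs both feedback conditions in `summaries`")
  }
  nm <- theta_names(experiment)
  starts <- starts %||% start_grid(experiment)
  stopifnot(ncol(starts) == length(nm))

  # precomputed per-condition coefficients so the objective is plain
  # vector arithmetic: mu = F_th * c_mu, sigma^2 = sigma_F^2 * c_F +
  # c_P * sigma_P^2 (with the feedback-matched sigma_P)
  kl <- summaries$K_left
  kr <- summaries$K_right
  bilateral <- kl > 0 & kr > 0
  c_mu <- ifelse(bilateral, (1 - w) * (-1 / kl) + w / kr,
                 ifelse(kr > 0, 1 / kr, -1 / kl))
  c_F <- ifelse(bilateral, (1 - w)^2 / kl^2 + w^2 / kr^2,
                1 / pmax(kl, kr)^2)
  c_P <- ifelse(bilateral, (1 - w)^2 + w^2, 1)
  fp <- summaries$feedback == "present"
  obs_bias <- summaries$bias_m
  obs_sd <- summaries$sd_m
  # objective scaled to ~cm^2 magnitudes for optimizer conditioning
  obj <- function(theta) {
    sP <- if (experiment == "exp1") ifelse(fp, theta[3], theta[4]) else theta[3]
    mu <- theta[1] * c_mu
    sig <- sqrt(theta[2]^2 * c_F + c_P * sP^2)
    1e6 * sum((obs_bias - mu)^2 + (obs_sd - sig)^2)
  }
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    nlminb(starts[i, ], obj, lower = rep(0, length(nm)),
           upper = c(2, 1, rep(0.2, length(nm) - 2)),
           control = list(iter.max = 500, eval.max = 2000,
                          abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-12))
  })
  ss <- purrr::map_dbl(runs, function(r) r$objective / 1e6)
  best_ss <- min(ss)
  tied <- which(ss <= best_ss + 1e-12)
  pick <- tied[which.min(purrr::map_dbl(runs[tied], function(r) r$par[1]))]
  best <- runs[[pick]]
  theta <- setNames(pmax(best$par, 0), nm)
  params <- theta_to_params(theta, experiment, w)
  # PORT labels flat-curvature optima "singular convergence"; treat any
  # *-convergence message as converged, and fall back on agreement of
  # several independent starts at the same SS
  ok_msg <- "relative convergence|X-convergence|function convergence|singular convergence"
  converged <- any(purrr::map_lgl(runs[tied], function(r) {
    r$convergence == 0 || grepl(ok_msg, r$message %||% "")
  })) || length(tied) >= 2
  if (!converged) {
    warn("no optimizer start reported convergence; returning the best point found")
  }
  pred <- bisection_predict(summaries, params)
  y <- c(summaries$bias_m, summaries$sd_m)
  yhat <- c(pred$mu_x, pred$sigma_x)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("zero total variance in the (bias, SD) vector; R^2 undefined")
  structure(
    list(params = params, experiment = experiment, ss = best_ss,
         r2 = 1 - sum((y - yhat)^2) / ss_tot,
         n_points = length(y), converged = converged,
         starts_tried = nrow(starts), data = summaries,
         fitted = dplyr::select(pred, dplyr::any_of(
           c("condition_id", "experiment", "K_left", "K_right", "side",
             "feedback", "bias_m", "sd_m", "mu_x", "sigma_x")))),
    class = "bisect_fit"
  )
}

#' Goodness of fit of a bisection-model fit
#'
#' Coefficient of determination over the concatenated (bias, SD) vector —
#' the same vector the least-squares objective minimizes — with the total
#' sum of squares taken about that vector's mean.
#'
#' @param fit a `bisect_fit` object.
#' @return R^2 (dimensionless, <= 1).
#' @export
goodness_r2 <- function(fit) {
  stopifnot(inherits(fit, "bisect_fit"))
  fit$r2
}

#' @export
print.bisect_fit <- function(x, ...) {
  cat(sprintf("<bisect_fit> %s bisection model, %d data points\n",
              x$experiment, x$n_points))
  p <- x$params
  cat(sprintf("  F_th = %.4g N, sigma_F = %.4g N\n", p$F_th, p$sigma_F))
  if (x$experiment == "exp1") {
    cat(sprintf("  sigma_P = %.4g cm (feedback present), %.4g cm (absent)\n",
                100 * p$sigma_P_fp, 100 * p$sigma_P_fa))
  } else {
    cat(sprintf("  sigma_P = %.4g cm\n", 100 * p$sigma_P))
  }
  cat(sprintf("  SS = %.4g m^2, R^2 = %.4g, converged = %s (%d starts)\n",
              x$ss, x$r2, x$converged, x$starts_tried))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bisect_fit <- function(x, ...) {
  p <- x$params
  if (x$experiment == "exp1") {
    tibble::tibble(
      term = c("F_th", "sigma_F", "sigma_P_fp", "sigma_P_fa"),
      estimate = c(p$F_th, p$sigma_F, p$sigma_P_fp, p$sigma_P_fa),
      unit = c("N", "N", "m", "m")
    )
  } else {
    tibble::tibble(
      term = c("F_th", "sigma_F", "sigma_P"),
      estimate = c(p$F_th, p$sigma_F, p$sigma_P),
      unit = c("N", "N", "m")
    )
  }
}

#' @exportS3Method generics::glance
glance.bisect_fit <- function(x, ...) {
  tibble::tibble(ss = x$ss, r2 = x$r2, n_points = x$n_points,
                 converged = x$converged, starts_tried = x$starts_tried)
}

#' @exportS3Method generics::augment
augment.bisect_fit <- function(x, ...) {
  x$fitted
}
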