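test_that("the joint objective is zero at the generating parameters and grows with residuals", {
  dat <- model_summaries("exp2")
  expect_equal(bisection_loss(dat, truth_exp2()), 0)
  one <- dat[1, ]
  shifted <- dplyr::mutate(one, bias_m = bias_m + 0.01)
  expect_equal(bisection_loss(shifted, truth_exp2()), 1e-4)
  # perturbing any parameter away from truth strictly increases the loss
  for (delta in list(c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.002))) {
    p <- bisection_params(0.12 + delta[1], 0.062 + delta[2],
                          sigma_P = 0.0051 + delta[3])
    expect_gt(bisection_loss(dat, p), 0)
  }
})

test_that("noiseless bilateral round-trip recovers all four parameters to 0.1%", {
  fit <- fit_bisection(model_summaries("exp1"))
  expect_true(fit$converged)
  expect_rel_error(fit$params$F_th, 0.085, 1e-3)
  expect_rel_error(fit$params$sigma_F, 0.052, 1e-3)
  expect_rel_error(fit$params$sigma_P_fp, 0.0093, 1e-3)
  expect_rel_error(fit$params$sigma_P_fa, 0.012, 1e-3)
  expect_lt(fit$ss, 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 28)
})

test_that("noiseless unilateral round-trip recovers all three parameters to 0.1%", {
  fit <- fit_bisection(model_summaries("exp2"))
  expect_true(fit$converged)
  expect_rel_error(fit$params$F_th, 0.12, 1e-3)
  expect_rel_error(fit$params$sigma_F, 0.062, 1e-3)
  expect_rel_error(fit$params$sigma_P, 0.0051, 1e-3)
  expect_equal(fit$n_points, 12)
})

test_that("the optimizer never loses to an exhaustive coarse grid search", {
  grid2 <- tidyr::crossing(F_th = seq(0.01, 0.3, by = 0.01),
                           sigma_F = seq(0, 0.15, by = 0.01),
                           sigma_P = seq(0, 0.03, by = 0.002))
  # noiseless and noisy unilateral datasets
  dat <- model_summaries("exp2")
  expect_lte(fit_bisection(dat)$ss, oracle_best_ss(dat, grid2))
  co <- simulate_cohort("exp2", 12, truth_exp2(), seed = 23)
  noisy <- summarize_group(summarize_conditions(reject_outliers(
    trials_from_endpoints(co))))
  expect_lte(fit_bisection(noisy)$ss, oracle_best_ss(noisy, grid2))

  grid1 <- tidyr::crossing(F_th = seq(0.01, 0.3, by = 0.02),
                           sigma_F = seq(0, 0.15, by = 0.015),
                           sigma_P_fp = seq(0, 0.03, by = 0.003),
                           sigma_P_fa = seq(0, 0.03, by = 0.003))
  dat1 <- model_summaries("exp1")
  expect_lte(fit_bisection(dat1)$ss, oracle_best_ss(dat1, grid1))
})

test_that("R^2 is the coefficient of determination over the joint (bias, SD) vector", {
  co <- simulate_cohort("exp1", 12, truth_exp1(), seed = 31)
  grp <- summarize_group(summarize_conditions(reject_outliers(
    trials_from_endpoints(co))))
  fit <- fit_bisection(grp)
  y <- c(grp$bias_m, grp$sd_m)
  yhat <- c(fit$fitted$mu_x, fit$fitted$sigma_x)
  expect_equal(goodness_r2(fit), 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_lt(fit$r2, 1)
  expect_gt(fit$r2, 0.8) # the model explains model-generated noisy data well
})

test_that("fits survive a round trip through the cm-based report files", {
  grp <- model_summaries("exp2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(grp, path)
  back <- read_summary_csv(path)
  f1 <- tidy(fit_bisection(grp))
  f2 <- tidy(fit_bisection(back))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("fit input validation names the problem", {
  dat <- model_summaries("exp1")
  expect_error(fit_bisection(dat[dat$feedback == "present", ]),
               "both feedback conditions")
  expect_error(fit_bisection(dplyr::mutate(dat, experiment = "exp3")), "exp")
  mixed <- dplyr::bind_rows(model_summaries("exp1"), model_summaries("exp2"))
  expect_error(fit_bisection(mixed), "single experiment")
})

test_that("broom-style accessors expose parameters, diagnostics and fitted values", {
  fit <- fit_bisection(model_summaries("exp2"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unit"))
  expect_equal(td$term, c("F_th", "sigma_F", "sigma_P"))
  gl <- glance(fit)
  expect_named(gl, c("ss", "r2", "n_points", "converged", "starts_tried"))
  expect_equal(gl$starts_tried, nrow(fieldcenter:::start_grid("exp2")))
  au <- augment(fit)
  expect_equal(nrow(au), 6)
  expect_true(all(c("bias_m", "sd_m", "mu_x", "sigma_x") %in% names(au)))
})
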