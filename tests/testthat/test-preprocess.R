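test_that("endpoint extraction averages the final 100 ms", {
  t <- seq(0, 2, by = 1 / 250)
  expect_equal(extract_endpoint(t, rep(0.02, length(t))), 0.02)
  # linear ramp: mean of the last 25 samples, computed directly
  x <- 0.001 * t
  expect_equal(extract_endpoint(t, x), mean(tail(x, 25)))
  expect_error(extract_endpoint(c(0, 0.05), c(0, 0)), "shorter")
})

test_that("zero-crossings are located by linear interpolation", {
  expect_equal(zero_crossings(c(0.009, 0.011), c(-0.01, 0.01)), 0.010)
  # exact-zero sample between opposite signs counts once, at its position
  expect_equal(zero_crossings(c(0, 0.01, 0.02), c(-0.1, 0, 0.1)), 0.01)
  # noiseless symmetric bilateral field: every crossing at the true center
  x <- seq(-0.05, 0.05, by = 0.001)
  xx <- c(x, rev(x), x)
  f <- field_force(xx, 0.0123, 8, 8)
  zc <- zero_crossings(xx, f)
  expect_gte(length(zc), 2)
  expect_equal(zc, rep(0.0123, length(zc)), tolerance = 1e-12)
  expect_error(estimate_center_exp1(c(0, 0.01), c(0.1, 0.2), bilateral = FALSE),
               "bilateral")
  expect_error(estimate_center_exp1(c(0, 0.01), c(0.1, 0.2)), "zero-crossing")
})

test_that("leave-one-out rejection removes deviants and honours the run-length rule", {
  base <- tibble::tibble(
    condition_id = "c1",
    trial = 1:6,
    error_m = c(0.001, -0.001, 0.0005, -0.0005, 0, 0.05),
    max_flag_run_s = 0
  )
  out <- reject_outliers(base)
  expect_equal(out$kept, c(rep(TRUE, 5), FALSE))
  expect_equal(out$reject_reason[6], "deviant")

  # all endpoints equal: nothing rejected
  same <- dplyr::mutate(base, error_m = 0.002)
  expect_true(all(reject_outliers(same)$kept))

  # zero-SD condition with one differing point rejects that point
  zs <- dplyr::mutate(base, error_m = c(rep(0.002, 5), 0.0021))
  expect_equal(reject_outliers(zs)$kept, c(rep(TRUE, 5), FALSE))

  # flagged run of exactly 0.5 s is kept ("more than 0.5 s" rejects)
  fl <- dplyr::mutate(base, error_m = 0.001,
                      max_flag_run_s = c(0.5, 0.504, rep(0, 4)))
  out <- reject_outliers(fl)
  expect_equal(out$kept, c(TRUE, FALSE, rep(TRUE, 4)))
  expect_equal(out$reject_reason[2], "flag_run")

  # fewer than 3 trials: criterion 2 is not applied
  small <- base[1:2, ]
  expect_true(all(reject_outliers(small)$kept))
})

test_that("rejection is single-pass: re-running on kept trials rejects nothing new", {
  withr::local_seed(8)
  trials <- tibble::tibble(
    condition_id = rep(c("a", "b"), each = 30),
    trial = 1:60,
    error_m = c(rnorm(29, 0, 0.005), 0.2, rnorm(29, 0, 0.005), -0.15),
    max_flag_run_s = 0
  )
  once <- reject_outliers(trials)
  expect_equal(sum(!once$kept), 2)
  again <- reject_outliers(dplyr::filter(once, kept))
  expect_true(all(again$kept))
})

test_that("condition and group summaries compute bias, SD and SE as defined", {
  trials <- tibble::tibble(
    participant = rep(1:2, each = 2),
    condition_id = "c", experiment = "exp2",
    K_left = 0, K_right = 8, side = "right", feedback = "none",
    error_m = c(0.01, -0.01, 0.02, 0.00)
  )
  cond <- summarize_conditions(trials)
  expect_equal(cond$bias_m, c(0, 0.01))
  expect_equal(cond$sd_m, c(sqrt(2) / 100, sqrt(2) / 100))
  expect_equal(cond$n_trials, c(2, 2))
  grp <- summarize_group(cond)
  expect_equal(grp$bias_m, 0.005)
  expect_equal(grp$se_bias_m, sd(c(0, 0.01)) / sqrt(2))
  expect_equal(grp$sd_m, sqrt(2) / 100)
  expect_equal(grp$n_participants, 2)
  expect_error(summarize_conditions(trials[1, ]), "fewer than 2")
})

test_that("shifting all positions and the center leaves biases unchanged", {
  d <- generate_design("exp1", 13)
  ep <- simulate_endpoints(d, truth_exp1(), "bisection", seed = 14)
  t1 <- summarize_conditions(trials_from_endpoints(ep))
  shifted <- dplyr::mutate(ep, center_m = center_m + 0.05,
                           start_m = start_m + 0.05,
                           endpoint_m = endpoint_m + 0.05)
  t2 <- summarize_conditions(trials_from_endpoints(shifted))
  expect_equal(t1$bias_m, t2$bias_m)
  expect_equal(t1$sd_m, t2$sd_m)
})

test_that("the full chain on noiseless records returns the generator's bias exactly", {
  quiet <- bisection_params(F_th = 0.085, sigma_F = 0, sigma_P_fp = 0,
                            sigma_P_fa = 0)
  d <- generate_design("exp1", 15)
  d <- d[d$condition_id %in% unique(d$condition_id)[1:2], ]
  ep <- simulate_endpoints(d, quiet, "bisection", seed = 16)
  s <- simulate_trajectory(ep)
  trials <- reject_outliers(preprocess_trials(s, d))
  cond <- summarize_conditions(trials)
  pred <- bisection_predict(cond, quiet)
  # errors are referenced to per-trial zero-crossing centers, which sit at
  # the rendered center up to interpolation across the stiffness kink
  expect_lt(max(abs(cond$bias_m - pred$mu_x)), 5e-4)
  expect_lt(max(cond$sd_m), 5e-4)
  # endpoint-level path (designed-center reference) is exact
  cond2 <- summarize_conditions(trials_from_endpoints(ep))
  expect_equal(cond2$bias_m, pred$mu_x)
  expect_equal(cond2$sd_m, rep(0, nrow(cond2)))
})

test_that("12 simulated participants reproduce the generative group biases", {
  co <- simulate_cohort("exp1", n_participants = 12, params = truth_exp1(),
                        seed = 17)
  grp <- summarize_group(summarize_conditions(reject_outliers(
    trials_from_endpoints(co))))
  pred <- bisection_predict(grp, truth_exp1())
  z <- abs(grp$bias_m - pred$mu_x) / grp$se_bias_m
  expect_gte(sum(z <= 2), 12) # most conditions within 2 SE of the model bias
  expect_true(all(z <= 4))
})
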