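test_that("noiseless endpoints sit at center plus the model bias", {
  quiet1 <- bisection_params(F_th = 0.085, sigma_F = 0, sigma_P_fp = 0,
                             sigma_P_fa = 0)
  d <- generate_design("exp1", 3)
  ep <- simulate_endpoints(d, quiet1, "bisection", seed = 1)
  sym <- ep[ep$K_left == 8 & ep$K_right == 8, ]
  expect_equal(sym$endpoint_m, sym$center_m)

  quiet2 <- bisection_params(F_th = 0.12, sigma_F = 0, sigma_P = 0)
  d2 <- generate_design("exp2", 3)
  ep2 <- simulate_endpoints(d2, quiet2, "bisection", seed = 1)
  r8 <- ep2[ep2$K_right == 8, ]
  expect_equal(r8$endpoint_m, r8$center_m + 0.015)
})

test_that("endpoint draws are reproducible under a fixed seed", {
  d <- generate_design("exp2", 4)
  p <- truth_exp2()
  expect_identical(simulate_endpoints(d, p, "bisection", seed = 9),
                   simulate_endpoints(d, p, "bisection", seed = 9))
  co <- simulate_cohort("exp1", n_participants = 2, seed = 5)
  expect_identical(co, simulate_cohort("exp1", n_participants = 2, seed = 5))
})

test_that("10^4 simulated endpoints reproduce the generative mean and SD", {
  # unilateral K = 8 on the right, unilateral-task parameter set
  p <- truth_exp2()
  d <- generate_design("exp2", 21)
  row <- d[d$K_right == 8, ][rep(1, 1e4), ]
  ep <- simulate_endpoints(row, p, "bisection", seed = 42)
  err <- ep$endpoint_m - ep$center_m
  sigma <- sqrt(0.062^2 / 64 + 0.0051^2)
  expect_rel_error(sd(err), sigma, 0.03)
  expect_lt(abs(mean(err) - 0.12 / 8), 0.03 * sigma)
})

test_that("trajectories settle exactly on the endpoint and sweep across bilateral centers", {
  d <- generate_design("exp1", 6)[1:8, ]
  ep <- simulate_endpoints(d, truth_exp1(), "bisection", seed = 2)
  s <- simulate_trajectory(ep)
  got <- extract_endpoints(s)
  expect_equal(got$endpoint_m[order(got$trial)],
               ep$endpoint_m[order(ep$trial)], tolerance = 1e-9)
  for (tr in ep$trial) {
    zc <- zero_crossings(s$x_m[s$trial == tr], s$force_N[s$trial == tr])
    expect_gte(length(zc), 2)
  }
  expect_error(simulate_trajectory(ep, exploration_profile("exp1", duration_s = -1)),
               "duration")
})

test_that("rendered forces follow the field law along the trajectory", {
  d <- generate_design("exp2", 8)[1:4, ]
  ep <- simulate_endpoints(d, truth_exp2(), "bisection", seed = 3)
  s <- simulate_trajectory(ep)
  by_trial <- split(s, s$trial)
  for (tr in names(by_trial)) {
    row <- ep[ep$trial == as.integer(tr), ]
    expect_equal(by_trial[[tr]]$force_N,
                 field_force(by_trial[[tr]]$x_m, row$center_m,
                             row$K_left, row$K_right))
  }
  # attractive unilateral field: zero outside the object, restoring inside
  row <- ep[1, ]
  inside <- if (row$side == "right") row$center_m + 0.02 else row$center_m - 0.02
  outside <- 2 * row$center_m - inside
  f_in <- field_force(inside, row$center_m, row$K_left, row$K_right)
  expect_equal(field_force(outside, row$center_m, row$K_left, row$K_right), 0)
  expect_equal(abs(f_in), max(row$K_left, row$K_right) * 0.02)
  expect_lt(f_in * (inside - row$center_m), 0) # pushes back toward the edge
})

test_that("flagged epochs propagate into trial rejection downstream", {
  d <- generate_design("exp1", 10)[1:6, ]
  ep <- simulate_endpoints(d, truth_exp1(), "bisection", seed = 4)
  s <- simulate_trajectory(ep)
  s <- flag_epoch(s, trial = 2, from_s = 1, duration_s = 0.6)
  trials <- reject_outliers(preprocess_trials(s, d))
  expect_false(trials$kept[trials$trial == 2])
  expect_equal(trials$reject_reason[trials$trial == 2], "flag_run")
  expect_true(all(trials$kept[trials$trial != 2]))
})
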