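test_that("bisection bias matches hand evaluations of the bilateral and unilateral forms", {
  expect_equal(bisection_bias(8, 8, F_th = 0.085), 0)
  expect_equal(bisection_bias(16, 4, F_th = 0.1), 0.5 * (-0.1 / 16 + 0.1 / 4))
  expect_equal(bisection_bias(16, 4, F_th = 0.1), 0.009375)
  expect_equal(bisection_bias(0, 8, F_th = 0.12), 0.015)
  expect_equal(bisection_bias(8, 0, F_th = 0.12), -0.015)
  expect_error(bisection_bias(0, 0, F_th = 0.1), "at least one spring")
})

test_that("bisection SD matches hand evaluations and vanishes without noise", {
  expect_equal(bisection_sd(16, 4, sigma_F = 0, sigma_P = 0), 0)
  expect_equal(bisection_sd(8, 8, sigma_F = 0.052, sigma_P = 0.0093),
               sqrt(0.25 * (2 * 0.052^2 / 64 + 2 * 0.0093^2)))
  expect_equal(bisection_sd(0, 8, sigma_F = 0.062, sigma_P = 0.0051),
               sqrt(0.062^2 / 64 + 0.0051^2))
})

test_that("mirroring a field negates the bias and preserves the SD", {
  pairs <- exp1_conditions()
  for (i in seq_len(nrow(pairs))) {
    kl <- pairs$K_left[i]; kr <- pairs$K_right[i]
    expect_equal(bisection_bias(kl, kr, 0.085), -bisection_bias(kr, kl, 0.085))
    expect_equal(bisection_sd(kl, kr, 0.05, 0.01),
                 bisection_sd(kr, kl, 0.05, 0.01))
  }
  expect_equal(bisection_bias(0, 8, 0.1), -bisection_bias(8, 0, 0.1))
})

test_that("unilateral |bias| decreases in K and increases in F_th; SD is monotone in its inputs", {
  Ks <- c(4, 8, 16)
  b <- abs(bisection_bias(0, Ks, F_th = 0.1))
  expect_true(all(diff(b) < 0))
  expect_true(all(diff(abs(bisection_bias(0, 8, F_th = c(0.05, 0.1, 0.2)))) > 0))
  # SD nonincreasing when each K grows, nondecreasing in each noise SD
  expect_true(all(diff(bisection_sd(Ks, 4, 0.05, 0.01)) <= 0))
  expect_true(all(diff(bisection_sd(4, Ks, 0.05, 0.01)) <= 0))
  expect_true(all(diff(bisection_sd(8, 8, c(0.01, 0.05, 0.1), 0.01)) >= 0))
  expect_true(all(diff(bisection_sd(8, 8, 0.05, c(0.001, 0.01, 0.02))) >= 0))
})

test_that("per-condition predictions pick the feedback-matched positional noise", {
  pred <- bisection_predict(exp1_conditions(), truth_exp1())
  expect_named(pred, c(names(exp1_conditions()), "mu_x", "sigma_x"))
  sym <- pred[pred$K_left == 8 & pred$K_right == 8, ]
  expect_equal(sym$mu_x, c(0, 0))
  fp <- sym$sigma_x[sym$feedback == "present"]
  fa <- sym$sigma_x[sym$feedback == "absent"]
  expect_lt(fp, fa) # visual feedback shrinks positional noise
  expect_equal(fp, sqrt(0.25 * (2 * 0.052^2 / 64 + 2 * 0.0093^2)))
  # a params object without the needed sigma errors out
  expect_error(bisection_predict(exp1_conditions(), truth_exp2()),
               "positional-noise")
})

test_that("parameter constructor validates its invariants", {
  expect_error(bisection_params(-0.1), "F_th")
  expect_error(bisection_params(0.1, sigma_F = -1), "sigma_F")
  expect_error(bisection_params(0.1, sigma_P = -0.01), "positional")
  expect_error(bisection_params(0.1, w = 1.5), "w")
})
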