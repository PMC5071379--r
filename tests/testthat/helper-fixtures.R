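# Shared fixtures: generating parameter sets and noiseless model-generated
# group summaries for round-trip fitting, plus a brute-force grid-search
# oracle for the least-squares objective, coded directly from the model
# equations (independently of the package's fitting path).

truth_exp1 <- function() {
  bisection_params(F_th = 0.085, sigma_F = 0.052,
                   sigma_P_fp = 0.0093, sigma_P_fa = 0.012)
}

truth_exp2 <- function() {
  bisection_params(F_th = 0.12, sigma_F = 0.062, sigma_P = 0.0051)
}

model_summaries <- function(experiment, params = NULL) {
  params <- params %||% if (experiment == "exp1") truth_exp1() else truth_exp2()
  conds <- if (experiment == "exp1") exp1_conditions() else exp2_conditions()
  dplyr::rename(bisection_predict(conds, params),
                bias_m = mu_x, sd_m = sigma_x)
}

# Brute-force SS oracle: evaluates the joint bias+SD objective on an
# explicit parameter grid with the model equations written out, and
# returns the smallest SS found.
oracle_best_ss <- function(summaries, grid) {
  kl <- summaries$K_left
  kr <- summaries$K_right
  uni <- kl == 0 | kr == 0
  ss_one <- function(F_th, sigma_F, sP_row) {
    mu <- ifelse(uni,
                 ifelse(kr > 0, F_th / kr, -F_th / kl),
                 0.5 * (-F_th / kl + F_th / kr))
    sig <- ifelse(uni,
                  sqrt(sigma_F^2 / pmax(kl, kr)^2 + sP_row^2),
                  sqrt((sigma_F^2 / kl^2 + sigma_F^2 / kr^2 + 2 * sP_row^2) / 4))
    sum((summaries$bias_m - mu)^2 + (summaries$sd_m - sig)^2)
  }
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sP_row <- if ("sigma_P" %in% names(grid)) {
      rep(g$sigma_P, nrow(summaries))
    } else {
      ifelse(summaries$feedback == "present", g$sigma_P_fp, g$sigma_P_fa)
    }
    ss_one(g$F_th, g$sigma_F, sP_row)
  }, numeric(1))
  min(vals)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
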