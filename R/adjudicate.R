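#' Adjudicate bisection vs stiffness model from measured biases
#'
#' Compares measured group biases with the bisection model's prediction
#' band over the literature range of force detection thresholds
#' (0.05-0.1 N by default). Because the stiffness model predicts biases
#' anywhere between the bisection prediction and zero (depending on the
#' unknown probe depth), biases systematically *below* the band favor the
#' stiffness model, while biases inside (or above) it are consistent with
#' the bisection model. Bilateral summaries are first averaged across the
#' two feedback conditions, since the band does not depend on feedback.
#'
#' Verdicts compare bias magnitudes with the band's magnitude interval:
#' `below_band` if `|bias| < min(|band|)`, `above_band` if
#' `|bias| > max(|band|)`, else `in_band` (band edges inclusive). A
#' symmetric field has a `[0, 0]` band, so a zero bias is `in_band`.
#' The overall call favors the stiffness model iff more than half of the
#' conditions with a nonzero band fall below it.
#'
#' @param summaries group-summary tibble with condition columns and
#'   `bias_m` (m).
#' @param F_th_range literature threshold range, N.
#' @return An object of class `field_adjudication`: a tibble with one row
#'   per (feedback-averaged) condition — `bias_m`, `band_lo`, `band_hi`,
#'   `verdict` — with attribute `overall` (`"favors_stiffness"` or
#'   `"consistent_with_bisection"`).
#' @export
adjudicate <- function(summaries, F_th_range = c(0.05, 0.1)) {
  summaries <- tibble::as_tibble(summaries)
  check_conditions(summaries)
  stopifnot("bias_m" %in% names(summaries))
  avg <- summaries |>
    dplyr::group_by(.data$experiment, .data$K_left, .data$K_right, .data$side) |>
    dplyr::summarise(bias_m = mean(.data$bias_m), .groups = "drop") |>
    dplyr::mutate(feedback = "n/a")
  band <- prediction_band(avg, model = "bisection", F_th_range = F_th_range)
  eps <- 1e-12
  band <- band |>
    dplyr::mutate(
      mag = abs(.data$bias_m),
      mag_lo = pmin(abs(.data$band_lo), abs(.data$band_hi)),
      mag_hi = pmax(abs(.data$band_lo), abs(.data$band_hi)),
      verdict = dplyr::case_when(
        .data$mag < .data$mag_lo - eps ~ "below_band",
        .data$mag > .data$mag_hi + eps ~ "above_band",
        TRUE ~ "in_band"
      )
    ) |>
    dplyr::select(-"mag", -"mag_lo", -"mag_hi", -"feedback")
  informative <- band$band_lo != 0 | band$band_hi != 0
  overall <- if (sum(informative) > 0 &&
                 mean(band$verdict[informative] == "below_band") > 0.5) {
    "favors_stiffness"
  } else {
    "consistent_with_bisection"
  }
  structure(band, class = c("field_adjudication", class(band)),
            overall = overall)
}

#' @export
print.field_adjudication <- function(x, ...) {
  cat("<field_adjudication> overall:", attr(x, "overall"), "\n")
  NextMethod()
  invisible(x)
}

#' Overall adjudication call
#' @param x a `field_adjudication` object.
#' @return `"favors_stiffness"` or `"consistent_with_bisection"`.
#' @export
overall_call <- function(x) {
  stopifnot(inherits(x, "field_adjudication"))
  attr(x, "overall")
}
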