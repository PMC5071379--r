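#' Condition tables for the two force-field experiments
#'
#' `exp1_conditions()` returns the bilateral-field design: seven
#' left/right spring-stiffness pairs (six asymmetric plus the symmetric
#' 8/8 pair) crossed with two visual-feedback conditions. The fields are
#' repulsive (they push the hand away from the center).
#' `exp2_conditions()` returns the unilateral design: a single attractive
#' spring of 4, 8 or 16 N/m on the left or the right of the center,
#' presented as the edge of a virtual object; visual feedback of hand
#' position is never given.
#'
#' @return A tibble with one row per condition and columns
#'   `condition_id`, `experiment` (`"exp1"` or `"exp2"`), `K_left` and
#'   `K_right` (spring stiffness, N/m; 0 where no spring is present),
#'   `side` (`"bilateral"`, `"left"`, `"right"`) and `feedback`
#'   (`"present"`, `"absent"`, or `"none"` for the unilateral experiment).
#' @examples
#' exp1_conditions()
#' exp2_conditions()
#' @export
exp1_conditions <- function() {
  pairs <- tibble::tribble(
    ~K_left, ~K_right,
    16, 4,
    16, 8,
    8, 4,
    4, 8,
    8, 16,
    4, 16,
    8, 8
  )
  out <- tidyr::crossing(pairs, feedback = c("present", "absent")) |>
    dplyr::arrange(match(paste(.data$K_left, .data$K_right),
                         paste(pairs$K_left, pairs$K_right)),
                   dplyr::desc(.data$feedback)) |>
    dplyr::mutate(
      experiment = "exp1",
      side = "bilateral",
      condition_id = sprintf("exp1_%02d_%02d_%s", .data$K_left, .data$K_right,
                             substr(.data$feedback, 1, 2))
    )
  dplyr::select(out, "condition_id", "experiment", "K_left", "K_right",
                "side", "feedback")
}

#' @rdname exp1_conditions
#' @export
exp2_conditions <- function() {
  out <- tidyr::crossing(K = c(4, 8, 16), side = c("left", "right")) |>
    dplyr::mutate(
      experiment = "exp2",
      K_left = ifelse(.data$side == "left", .data$K, 0),
      K_right = ifelse(.data$side == "right", .data$K, 0),
      feedback = "none",
      condition_id = sprintf("exp2_%02d_%s", .data$K, .data$side)
    )
  dplyr::select(out, "condition_id", "experiment", "K_left", "K_right",
                "side", "feedback")
}

# Shared validation for condition tables fed to prediction / fitting code.
check_conditions <- function(conditions) {
  needed <- c("experiment", "K_left", "K_right", "side", "feedback")
  missing <- setdiff(needed, names(conditions))
  if (length(missing) > 0) {
    abort(paste0("condition table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(conditions$K_left < 0 | conditions$K_right < 0)) {
    abort("spring stiffnesses must be >= 0")
  }
  if (any(conditions$K_left == 0 & conditions$K_right == 0)) {
    abort("each condition needs at least one spring with K > 0")
  }
  bilateral <- conditions$K_left > 0 & conditions$K_right > 0
  if (any(bilateral != (conditions$side == "bilateral"))) {
    abort("`side` is inconsistent with the stiffness columns (bilateral <=> both K > 0)")
  }
  if (any(conditions$side == "left" & conditions$K_left == 0) ||
      any(conditions$side == "right" & conditions$K_right == 0)) {
    abort("unilateral `side` must name the side whose spring is present")
  }
  invisible(conditions)
}
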