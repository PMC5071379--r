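#' Generate one participant's randomized trial design
#'
#' Emulates the trial-randomization rules of the two experiments. The
#' workspace is a 20 cm line; positions are in meters in the workspace
#' frame with 0 at the middle of the workspace.
#'
#' For the bilateral experiment (`"exp1"`), each of the 7 stiffness pairs
#' x 2 feedback conditions gets 6 trials: the field center is drawn
#' uniformly in each of three regions (-3..-1, -1..1, 1..3 cm from the
#' workspace middle), one start distance is drawn uniformly in 1..3 cm
#' per region, and that distance is used once on each side of the center
#' (mirrored starts), giving 3 regions x 2 start sides = 6 trials and 84
#' trials in total. For the unilateral experiment (`"exp2"`), each of the
#' 3 stiffnesses x 2 spring sides gets 3 regions x 2 repetitions = 6
#' trials (36 total); the start always lies outside the virtual object,
#' i.e. on the no-spring side of the center, at a distance of 1..3 cm.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed integer seed; the same seed reproduces the same design.
#' @return A tibble with one row per trial: the condition columns (see
#'   [exp1_conditions()]), `trial` (1..n within the participant),
#'   `region` (1..3), `start_side` (`"left"`/`"right"` of the center),
#'   `rep` (repetition index within region), `center_m` and `start_m`
#'   (workspace frame, m).
#' @examples
#' d <- generate_design("exp1", seed = 1)
#' nrow(d)                       # 84
#' dplyr::count(d, condition_id) # 6 per condition
#' @export
generate_design <- function(experiment = c("exp1", "exp2"), seed) {
  experiment <- match.arg(experiment)
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::local_seed(as.integer(seed))
  region_bounds <- list(c(-0.03, -0.01), c(-0.01, 0.01), c(0.01, 0.03))
  conds <- if (experiment == "exp1") exp1_conditions() else exp2_conditions()

  one_condition <- function(cond) {
    purrr::map_dfr(1:3, function(region) {
      lo <- region_bounds[[region]][1]
      hi <- region_bounds[[region]][2]
      center <- stats::runif(1, lo, hi)
      if (cond$experiment == "exp1") {
        d <- stats::runif(1, 0.01, 0.03)
        tibble::tibble(
          region = region,
          start_side = c("left", "right"),
          rep = 1:2,
          center_m = center,
          start_m = center + c(-d, d)
        )
      } else {
        # start outside the object: on the side opposite the spring
        d <- stats::runif(2, 0.01, 0.03)
        s <- if (cond$side == "right") -1 else 1
        tibble::tibble(
          region = region,
          start_side = if (s < 0) "left" else "right",
          rep = 1:2,
          center_m = center,
          start_m = center + s * d
        )
      }
    })
  }

  out <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    cond <- conds[i, ]
    dplyr::bind_cols(cond[rep(1, 6), ], one_condition(cond))
  })
  dplyr::mutate(out, trial = dplyr::row_number(), .before = 1)
}
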