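#' File-based pipeline stages
#'
#' Re-runnable pipeline stages binding simulation, preprocessing,
#' fitting, prediction and reporting through plain CSV/JSON files on
#' disk. Each stage writes a `manifest.json` (configuration, seed,
#' package version) from which the run can be reproduced exactly; a
#' rerun from the same manifest writes byte-identical CSVs. These are the
#' functions the `inst/cli/fieldcenter.R` command-line wrapper calls.
#'
#' @param config a `run_config` (see [read_run_config()]) or a path to a
#'   YAML config file.
#' @param out_dir output directory (created if missing).
#' @return the output directory (invisibly), or the loaded/produced
#'   object where noted.
#' @name pipeline
NULL

write_manifest <- function(out_dir, stage, config) {
  clean <- unclass(config)
  if (inherits(clean$params, "bisection_params")) {
    clean$params <- unclass(clean$params)
  }
  jsonlite::write_json(
    list(stage = stage, config = clean,
         package = "fieldcenter",
         version = as.character(utils::packageVersion("fieldcenter"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$experiment,
                            n_participants = config$n_participants,
                            params = config$params,
                            generator = config$generator,
                            seed = config$seed)
  design_cols <- setdiff(names(cohort), c("mu_x", "sigma_x", "endpoint_m"))
  write_design_csv(cohort[design_cols], file.path(out_dir, "designs.csv"),
                   meta = list(experiment = config$experiment, seed = config$seed))
  readr::write_csv(cohort, file.path(out_dir, "endpoints.csv"))
  write_sidecar(file.path(out_dir, "endpoints.csv"), "endpoints",
                list(generator = config$generator, units = "m"))
  if (config$trajectories) {
    samples <- purrr::map_dfr(
      split(cohort, cohort$participant),
      function(part) {
        dplyr::mutate(simulate_trajectory(part), participant = part$participant[1],
                      .before = 1)
      }
    )
    write_records_csv(samples, file.path(out_dir, "records.csv"),
                      meta = list(experiment = config$experiment))
  }
  write_manifest(out_dir, "simulate", config)
  message(sprintf("simulate: %d participants x %d trials (%s, %s) -> %s",
                  config$n_participants, max(cohort$trial),
                  config$experiment, config$generator, out_dir))
  invisible(out_dir)
}

#' @rdname pipeline
#' @param in_dir directory holding a [run_simulate()] output (or
#'   identically formatted real exports).
#' @export
run_preprocess <- function(in_dir, out_dir = in_dir) {
  design_path <- file.path(in_dir, "designs.csv")
  records_path <- file.path(in_dir, "records.csv")
  endpoints_path <- file.path(in_dir, "endpoints.csv")
  if (!file.exists(design_path)) {
    abort(paste0("missing input file: ", design_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- read_design_csv(design_path)
  if (!"participant" %in% names(design)) design$participant <- 1L
  trials <- if (file.exists(records_path)) {
    samples <- read_records_csv(records_path)
    if (!"participant" %in% names(samples)) samples$participant <- 1L
    purrr::map_dfr(
      unique(design$participant),
      function(p) {
        preprocess_trials(samples[samples$participant == p, ],
                          design[design$participant == p, ])
      }
    )
  } else if (file.exists(endpoints_path)) {
    trials_from_endpoints(read_records_csv(endpoints_path))
  } else {
    abort(paste0("no records.csv or endpoints.csv under ", in_dir))
  }
  trials <- reject_outliers(trials)
  rejections <- dplyr::filter(trials, !.data$kept)
  readr::write_csv(
    dplyr::select(rejections, dplyr::any_of(
      c("participant", "trial", "condition_id", "reject_reason"))),
    file.path(out_dir, "rejections.csv")
  )
  cond <- summarize_conditions(trials)
  grp <- summarize_group(cond)
  write_summary_csv(cond, file.path(out_dir, "condition_summaries.csv"))
  write_summary_csv(grp, file.path(out_dir, "group_summary.csv"))
  message(sprintf("preprocess: %d trials, %d rejected -> %s",
                  nrow(trials), nrow(rejections), out_dir))
  invisible(out_dir)
}

#' @rdname pipeline
#' @param summary_path path to a group-summary CSV
#'   (`group_summary.csv` from [run_preprocess()]).
#' @export
run_fit <- function(summary_path, out_dir = dirname(summary_path)) {
  if (!file.exists(summary_path)) {
    abort(paste0("missing input file: ", summary_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- read_summary_csv(summary_path)
  fit <- fit_bisection(summaries)
  jsonlite::write_json(
    list(params = unclass(fit$params), experiment = fit$experiment,
         ss_m2 = fit$ss, r2 = fit$r2, n_points = fit$n_points,
         converged = fit$converged, starts_tried = fit$starts_tried),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  report <- utils::capture.output({
    print(fit)
    cat("\nPer-condition data vs model (cm):\n")
    print(as.data.frame(dplyr::mutate(
      fit$fitted,
      dplyr::across(c("bias_m", "sd_m", "mu_x", "sigma_x"), function(v) round(100 * v, 3))
    )), row.names = FALSE)
  })
  writeLines(report, file.path(out_dir, "fit_report.txt"))
  if (!fit$converged) warn("fit did not report convergence (flagged in fit.json)")
  message(sprintf("fit: %s F_th=%.4g N, R^2=%.3f -> %s",
                  fit$experiment, fit$params$F_th, fit$r2, out_dir))
  invisible(fit)
}

#' @rdname pipeline
#' @param experiment experiment whose condition set to predict for.
#' @param F_th_range literature threshold range, N.
#' @export
run_predict <- function(experiment = c("exp1", "exp2"),
                        F_th_range = c(0.05, 0.1), out_dir = ".") {
  experiment <- match.arg(experiment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- if (experiment == "exp1") {
    dplyr::filter(exp1_conditions(), .data$feedback == "present") |>
      dplyr::mutate(feedback = "n/a")
  } else {
    exp2_conditions()
  }
  band <- prediction_band(conds, model = "bisection", F_th_range = F_th_range) |>
    dplyr::rename(band_lo_m = "band_lo", band_hi_m = "band_hi")
  write_summary_csv(band, file.path(out_dir, "prediction_band.csv"),
                    meta = list(F_th_range_N = F_th_range))
  message(sprintf("predict: %d conditions, F_th in [%.3g, %.3g] N -> %s",
                  nrow(band), min(F_th_range), max(F_th_range), out_dir))
  invisible(band)
}

#' @rdname pipeline
#' @param dir directory holding the outputs of the earlier stages.
#' @export
run_report <- function(dir) {
  grp_path <- file.path(dir, "group_summary.csv")
  if (!file.exists(grp_path)) abort(paste0("missing input file: ", grp_path))
  grp <- read_summary_csv(grp_path)
  fit <- run_fit(grp_path, out_dir = dir)
  adj <- adjudicate(grp)
  lines <- c(
    "force-field center estimation: combined report",
    "==============================================",
    "",
    sprintf("experiment: %s | conditions: %d | participants: %s",
            fit$experiment, nrow(grp),
            paste(unique(grp$n_participants %||% "?"), collapse = ",")),
    "",
    "Adjudication against the literature threshold band [0.05, 0.1] N:",
    sprintf("  overall: %s", overall_call(adj)),
    utils::capture.output(print(as.data.frame(dplyr::mutate(
      tibble::as_tibble(adj),
      dplyr::across(c("bias_m", "band_lo", "band_hi"), function(v) round(100 * v, 3))
    )), row.names = FALSE)),
    "",
    "Bisection-model fit:",
    utils::capture.output(print(fit))
  )
  writeLines(lines, file.path(dir, "report.txt"))
  message("report -> ", file.path(dir, "report.txt"))
  invisible(file.path(dir, "report.txt"))
}
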