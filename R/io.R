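#' Read and write pipeline tables
#'
#' Plain-CSV readers/writers for the pipeline's artifacts. Internal
#' computation is SI (meters); the human-facing summary tables are
#' written in centimeters, with unit-suffixed column names, and converted
#' back to meters on read. Each writer drops a JSON sidecar
#' (`<file>.meta.json`) describing the table.
#'
#' @param x table to write.
#' @param file CSV path.
#' @param meta optional named list merged into the sidecar.
#' @return the input (writers, invisibly) or a tibble (readers).
#' @name pipeline_io
NULL

write_sidecar <- function(file, kind, meta = list()) {
  side <- paste0(file, ".meta.json")
  payload <- c(list(kind = kind, package = "fieldcenter",
                    version = as.character(utils::packageVersion("fieldcenter"))),
               meta)
  jsonlite::write_json(payload, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

#' @rdname pipeline_io
#' @export
write_design_csv <- function(x, file, meta = list()) {
  readr::write_csv(x, file)
  write_sidecar(file, "trial_design", c(meta, list(units = "m")))
  invisible(x)
}

#' @rdname pipeline_io
#' @export
write_records_csv <- function(x, file, meta = list()) {
  readr::write_csv(x, file)
  write_sidecar(file, "trial_records",
                c(meta, list(units = "m_N_s", sample_rate_hz = 250)))
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_records_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
read_design_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

# meters -> centimeter columns for human-facing reports, and back
to_cm_cols <- function(x) {
  m_cols <- grep("_m$", names(x), value = TRUE)
  for (col in m_cols) {
    x[[sub("_m$", "_cm", col)]] <- 100 * x[[col]]
    x[[col]] <- NULL
  }
  x
}

from_cm_cols <- function(x) {
  cm_cols <- grep("_cm$", names(x), value = TRUE)
  for (col in cm_cols) {
    x[[sub("_cm$", "_m", col)]] <- x[[col]] / 100
    x[[col]] <- NULL
  }
  x
}

#' @rdname pipeline_io
#' @export
write_summary_csv <- function(x, file, meta = list()) {
  readr::write_csv(to_cm_cols(x), file)
  write_sidecar(file, "summary", c(meta, list(units = "cm")))
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_summary_csv <- function(file) {
  from_cm_cols(readr::read_csv(file, show_col_types = FALSE))
}

#' Run configuration
#'
#' Reads and validates a YAML run configuration for the pipeline. Fields:
#' `experiment` ("exp1"/"exp2"), `generator` ("bisection"/"stiffness"),
#' `n_participants`, `seed`, `trajectories` (logical; simulate full
#' per-sample records or endpoints only), and an optional `params` block
#' (`F_th`, `sigma_F`, `sigma_P_fp`, `sigma_P_fa`, `sigma_P`, in N and
#' m) overriding the generator defaults.
#'
#' @param path YAML file path.
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a named list of configuration values.
#' @export
validate_run_config <- function(config) {
  req <- function(field, ok, what) {
    if (is.null(config[[field]]) || !ok(config[[field]])) {
      abort(sprintf("config field `%s` %s", field, what))
    }
  }
  req("experiment", function(x) x %in% c("exp1", "exp2"),
      "must be \"exp1\" or \"exp2\"")
  config$generator <- config$generator %||% "bisection"
  req("generator", function(x) x %in% c("bisection", "stiffness"),
      "must be \"bisection\" or \"stiffness\"")
  config$n_participants <- config$n_participants %||% 12
  req("n_participants", function(x) is.numeric(x) && x >= 1,
      "must be a positive count")
  req("seed", function(x) is.numeric(x) && length(x) == 1,
      "must be a single integer")
  config$trajectories <- isTRUE(config$trajectories)
  if (!is.null(config$params)) {
    p <- config$params
    config$params <- bisection_params(
      F_th = p$F_th, sigma_F = p$sigma_F %||% 0,
      sigma_P_fp = p$sigma_P_fp %||% NA_real_,
      sigma_P_fa = p$sigma_P_fa %||% NA_real_,
      sigma_P = p$sigma_P %||% NA_real_,
      w = p$w %||% 0.5
    )
  } else {
    config$params <- default_bisection_params(config$experiment)
  }
  structure(config, class = "run_config")
}
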