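# File I/O: waveform and cohort CSVs -----------------------------------------

#' Write / read a pressure waveform CSV
#'
#' The on-disk format has a header `time_s,pressure_mmHg` and one row per
#' sample; time must be a strictly increasing uniform grid.
#'
#' @param waveform A `pressure_waveform`.
#' @param path File path.
#' @return `write_waveform_csv`: the path, invisibly. `read_waveform_csv`:
#'   a `pressure_waveform`.
#' @export
write_waveform_csv <- function(waveform, path) {
  check_waveform(waveform)
  write.csv(data.frame(time_s = waveform$time,
                       pressure_mmHg = waveform$pressure),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("time_s", "pressure_mmHg")
  if (!all(need %in% names(df)))
    stop("parse error: waveform CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s at row(s) %s", col,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0))
    stop("parse error: time_s must be strictly increasing", call. = FALSE)
  as_pressure_waveform(df$time_s, df$pressure_mmHg)
}

#' Write / read a patient-cohort CSV
#'
#' One row per patient; covariate columns are snake_case with units (e.g.
#' `nt_probnp_pg_ml`, `lvedp_mmhg`) plus `follow_up_years` and `event`.
#' `write_cohort_csv` optionally serialises the generating configuration
#' (the simulation ground truth) to a JSON sidecar `<path>.truth.json`.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @param truth_sidecar Logical; write the truth sidecar when the cohort
#'   carries a generating config.
#' @return `write_cohort_csv`: the path, invisibly. `read_cohort_csv`: a
#'   `cohort` data frame.
#' @export
write_cohort_csv <- function(cohort, path, truth_sidecar = FALSE) {
  df <- as.data.frame(cohort)
  write.csv(df, path, row.names = FALSE)
  truth <- attr(cohort, "truth")
  if (truth_sidecar && !is.null(truth)) {
    jsonlite::write_json(
      unclass(truth)[setdiff(names(truth), c("covariate_specs",
                                             "invasive_specs"))],
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("follow_up_years", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: cohort CSV lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad))
    stop("parse error: event must be 0/1; offending row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$follow_up_years) | df$follow_up_years <= 0)
  if (length(bad))
    stop("parse error: follow_up_years must be positive; offending row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  structure(df, class = c("cohort", "data.frame"))
}
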