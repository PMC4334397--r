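# Readers and writers for the package's plain-text interchange formats.
# All numeric output uses 17 significant digits so every pair round-trips
# doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write / read an exam record as CSV
#'
#' Columns `time_s,pressure_cmH2O,flow_L_per_s`, one header line, UTF-8.
#'
#' @param exam An `exam_record`.
#' @param path File path.
#' @return `write_exam_csv` returns `path` invisibly; `read_exam_csv`
#'   returns an `exam_record`.
#' @export
write_exam_csv <- function(exam, path) {
  stopifnot(inherits(exam, "exam_record"))
  t <- (seq_along(exam$pressure) - 1) * exam$sampling_interval
  df <- data.frame(time_s = fmt_num(t),
                   pressure_cmH2O = fmt_num(exam$pressure),
                   flow_L_per_s = fmt_num(exam$flow))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_exam_csv
#' @export
read_exam_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric", fileEncoding = "UTF-8")
  need <- c("time_s", "pressure_cmH2O", "flow_L_per_s")
  if (!all(need %in% names(df))) {
    stopf("exam CSV must have columns %s", paste(need, collapse = ", "))
  }
  dt <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  exam_record(df$pressure_cmH2O, df$flow_L_per_s, dt)
}

#' Write / read an impedance spectrum as JSON
#'
#' Schema: `{frequencies_hz: [...], re: [...], im: [...], coherence: [...],
#' n_exams: k}`.
#'
#' @param spectrum An [impedance_spectrum].
#' @param path File path.
#' @export
write_spectrum_json <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  jsonlite::write_json(
    list(frequencies_hz = spectrum$frequencies,
         re = Re(spectrum$values), im = Im(spectrum$values),
         coherence = spectrum$coherence, n_exams = spectrum$n_exams),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  impedance_spectrum(x$frequencies_hz,
                     complex(real = x$re, imaginary = x$im),
                     x$coherence, n_exams = x$n_exams)
}

#' Write / read an eRIC fit as JSON
#'
#' @param fit An `eric_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "eric_fit"))
  jsonlite::write_json(
    list(R = fit$params$R, Rp = fit$params$Rp, I = fit$params$I,
         C = fit$params$C, Rt = fit$Rt, total_error = fit$total_error,
         relative_distance_pct = fit$relative_distance,
         converged = fit$converged, n_iterations = fit$n_iterations,
         gradient_norm = fit$gradient_norm, band = fit$band),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a cohort table as CSV
#'
#' @param table Cohort data frame from [build_cohort_table].
#' @param path File path.
#' @export
write_cohort_csv <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), c("subject_id", "group", "converged"))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  if ("converged" %in% names(df)) df$converged <- as.logical(df$converged)
  df
}

#' Write a statistical report as JSON
#'
#' Deterministic serialization (fixed key order, full precision), so a rerun
#' on the same table is byte-identical.
#'
#' @param report A `cohort_report`.
#' @param path File path.
#' @param config Optional [run_config] embedded for provenance.
#' @export
write_report_json <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  tabs <- report_tables(report)
  payload <- list(
    alpha = report$alpha,
    comparisons = tabs$comparisons,
    correlations = tabs$correlations,
    recovery = do.call(rbind, lapply(report$recovery, function(cr) {
      data.frame(truth = cr$x, fitted = cr$y, r = cr$r,
                 p_value = cr$p_value, n = cr$n, band = cr$band)
    })),
    notes = report$notes)
  if (!is.null(config)) {
    payload$provenance <- list(seed = config$seed, hash = config$hash)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}
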