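# Umbrella workflow: configuration, per-subject analysis, cohort table,
# and the simulate -> estimate -> indices -> fit -> statistics chain.

#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline uses. Units are
#' fixed package-wide: cmH2O, L/s, Hz, s.
#'
#' @param grid_start,grid_stop,grid_step Excitation/analysis grid (Hz);
#'   `grid_step` must divide the span.
#' @param sampling_rate Samples per second (Hz).
#' @param duration Exam length (s).
#' @param coherence_threshold Exam gate level, in (0, 1\].
#' @param coherence_band,fitting_band,regression_band,reactance_band Analysis
#'   bands (Hz); must lie within the grid.
#' @param n_control,n_cf Cohort sizes (study defaults 23 and 27).
#' @param seed Master seed; all randomness derives from it.
#' @param out_dir Output directory for artifacts (`NULL` = no files written).
#' @return Object of class `run_config`.
#' @export
run_config <- function(grid_start = 2, grid_stop = 32, grid_step = 2,
                       sampling_rate = 256, duration = 16,
                       coherence_threshold = 0.9,
                       coherence_band = c(4, 32),
                       fitting_band = c(4, 32),
                       regression_band = c(4, 16),
                       reactance_band = c(4, 32),
                       n_control = 23L, n_cf = 27L,
                       seed = 1L, out_dir = NULL) {
  if (grid_step <= 0 || (grid_stop - grid_start) %% grid_step != 0) {
    stopf("grid step must be positive and divide (stop - start)")
  }
  if (coherence_threshold <= 0 || coherence_threshold > 1) {
    stopf("coherence threshold must lie in (0, 1]")
  }
  grid <- seq(grid_start, grid_stop, by = grid_step)
  for (bnm in c("coherence_band", "fitting_band", "regression_band",
                "reactance_band")) {
    b <- get(bnm)
    if (length(b) != 2L || b[1] >= b[2] || b[1] < grid_start || b[2] > grid_stop) {
      stopf("%s must be an increasing pair within the grid", bnm)
    }
  }
  if (sampling_rate < 4 * grid_stop) {
    stopf("sampling rate below the 4x margin for %.3g Hz", grid_stop)
  }
  cfg <- structure(
    list(grid = grid, sampling_rate = sampling_rate, duration = duration,
         coherence_threshold = coherence_threshold,
         coherence_band = coherence_band, fitting_band = fitting_band,
         regression_band = regression_band, reactance_band = reactance_band,
         n_control = as.integer(n_control), n_cf = as.integer(n_cf),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
  cfg$hash <- fnv1a_hash(paste(deparse(cfg[setdiff(names(cfg), "out_dir")]),
                               collapse = ""))
  cfg
}

#' Analyze one subject end to end
#'
#' Estimates and gates the exam spectra, averages the satisfactory ones,
#' computes the eight FOT indices and the eRIC fit, and returns a one-row
#' data frame ready for the cohort table (with generator truth retained).
#'
#' @param subject A `virtual_subject`.
#' @param config A [run_config].
#' @param subject_id Identifier stored in the row.
#' @param group Group label stored in the row.
#' @return One-row `data.frame`.
#' @export
analyze_subject <- function(subject, config = run_config(),
                            subject_id = subject$seed, group = subject$profile_name) {
  sp <- subject_spectrum(subject, grid = config$grid,
                         threshold = config$coherence_threshold,
                         band = config$coherence_band)
  idx <- fot_indices(sp, reactance_band = config$reactance_band,
                     regression_band = config$regression_band)
  fit <- fit_eric(sp, band = config$fitting_band)
  data.frame(
    subject_id = as.character(subject_id), group = group,
    as.data.frame(idx),
    R = fit$params$R, Rp = fit$params$Rp, Rt = fit$Rt,
    I = fit$params$I, C = fit$params$C,
    total_error = fit$total_error,
    relative_distance = fit$relative_distance,
    converged = fit$converged,
    n_exams = sp$n_exams,
    truth_R = subject$truth$R, truth_Rp = subject$truth$Rp,
    truth_Rt = subject$truth$R + subject$truth$Rp,
    truth_I = subject$truth$I, truth_C = subject$truth$C,
    stringsAsFactors = FALSE)
}

#' Build the per-subject analysis table for one or more cohorts
#'
#' @param cohorts Named list of cohorts (lists of `virtual_subject`); names
#'   become group labels.
#' @param config A [run_config].
#' @return `data.frame`, one row per successfully analyzed subject, with an
#'   attribute `failures` listing per-subject errors.
#' @export
build_cohort_table <- function(cohorts, config = run_config()) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  rows <- list(); failures <- character(0)
  for (g in names(cohorts)) {
    for (k in seq_along(cohorts[[g]])) {
      subj <- cohorts[[g]][[k]]
      id <- sprintf("%s_%02d", g, k)
      res <- tryCatch(analyze_subject(subj, config, subject_id = id, group = g),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures, sprintf("%s: %s", id, res))
      } else {
        rows[[id]] <- res
      }
    }
  }
  if (!length(rows)) stopf("no subject could be analyzed: %s",
                           paste(failures, collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$subject_id)) stopf("duplicated subject ids")
  attr(out, "failures") <- failures
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a control and a CF cohort from the packaged profiles (the CF
#' profile calibrated to its R0 targets), analyzes every subject through the
#' spectral-estimation / index / model-fit chain, and produces the
#' statistical report. With `out_dir` set, writes the cohort table (CSV),
#' the report (JSON) and a manifest carrying the full configuration, its
#' hash and the master seed, so a rerun with the same config reproduces all
#' numbers exactly.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with `table`, `report`, `failures`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 2L)
  cohorts <- list(
    control = generate_cohort(fot_profile("control"), config$n_control,
                              seeds[1], sampling_rate = config$sampling_rate,
                              duration = config$duration, grid = config$grid),
    cf = generate_cohort(fot_profile("cf"), config$n_cf, seeds[2],
                         sampling_rate = config$sampling_rate,
                         duration = config$duration, grid = config$grid))
  table <- build_cohort_table(cohorts, config)
  report <- cohort_report(table)
  failures <- attr(table, "failures")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(table, file.path(config$out_dir, "cohort_table.csv"))
    write_report_json(report, file.path(config$out_dir, "report.json"),
                      config = config)
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config), "grid")],
           grid = config$grid, hash = config$hash,
           failures = failures),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = I(17), pretty = TRUE, null = "null")
  }
  if (length(failures)) {
    warning(sprintf("%d subject(s) failed: %s", length(failures),
                    paste(failures, collapse = "; ")), call. = FALSE)
  }
  invisible(list(table = table, report = report, failures = failures,
                 config = config))
}
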