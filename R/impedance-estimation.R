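#' Welch-averaged cross- and auto-spectra of an exam
#'
#' Splits the pressure and flow channels into overlapping Hann-windowed
#' segments, removes each segment's mean, and averages the raw cross- and
#' auto-spectra across segments. The impedance grid is read out at the FFT
#' bin nearest each requested frequency (with the default 4 s segments the
#' 2 Hz excitation grid falls exactly on bins).
#'
#' @param exam An `exam_record`.
#' @param grid Analysis frequencies (Hz).
#' @param segment_duration Segment length (s); sets the 1/T frequency
#'   resolution.
#' @param overlap Fractional segment overlap in \[0, 1).
#' @return An object of class `cross_spectra` with fields `frequencies`,
#'   `Gpv` (complex, pressure x flow), `Gvv`, `Gpp` (real, nonnegative) and
#'   `segment_count`.
#' @export
estimate_spectra <- function(exam, grid = seq(2, 32, by = 2),
                             segment_duration = 4, overlap = 0.5) {
  stopifnot(inherits(exam, "exam_record"))
  fs <- 1 / exam$sampling_interval
  nseg <- round(segment_duration * fs)
  step <- max(1L, round(nseg * (1 - overlap)))
  n <- length(exam$pressure)
  if (nseg + step > n) {
    stopf("exam too short for at least 2 averaging segments of %.3g s",
          segment_duration)
  }
  starts <- seq(1L, n - nseg + 1L, by = step)
  df <- fs / nseg
  bins <- round(grid / df)
  for (k in seq_along(grid)) {
    if (bins[k] < 1 || grid[k] >= fs / 2) {
      stopf("grid frequency %.3g Hz is not resolvable (resolution %.3g Hz, Nyquist %.3g Hz)",
            grid[k], df, fs / 2)
    }
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))  # periodic Hann
  seg_mat <- function(x) {
    m <- vapply(starts, function(s) {
      seg <- x[s:(s + nseg - 1L)]
      (seg - mean(seg)) * w
    }, numeric(nseg))
    stats::mvfft(m)
  }
  P <- seg_mat(exam$pressure)[bins + 1L, , drop = FALSE]
  V <- seg_mat(exam$flow)[bins + 1L, , drop = FALSE]
  norm <- fs * sum(w^2) * length(starts)
  structure(
    list(frequencies = grid,
         Gpv = rowSums(P * Conj(V)) / norm,
         Gvv = rowSums(Mod(V)^2) / norm,
         Gpp = rowSums(Mod(P)^2) / norm,
         segment_count = length(starts)),
    class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> %d lines (%.3g-%.3g Hz), %d segments\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$segment_count))
  invisible(x)
}

#' Impedance and coherence from averaged spectra
#'
#' The respiratory impedance is the ratio of the mean cross-spectrum between
#' pressure and flow to the mean flow auto-spectrum,
#' \eqn{Z_{rs}(f) = \bar G_{PV} / \bar G_{VV}}; the squared coherence
#' \eqn{\gamma^2 = |\bar G_{PV}|^2 / (\bar G_{PP}\bar G_{VV})} quantifies
#' how much of the signal pair is linearly related at each frequency.
#'
#' @param spectra A `cross_spectra` object.
#' @return An [impedance_spectrum] (with `n_exams = 1`).
#' @export
impedance_from_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "cross_spectra"))
  if (any(spectra$Gvv <= 0)) {
    stopf("zero flow auto-spectrum at %.3g Hz: degenerate excitation",
          spectra$frequencies[which(spectra$Gvv <= 0)[1]])
  }
  coh <- Mod(spectra$Gpv)^2 / (spectra$Gpp * spectra$Gvv)
  impedance_spectrum(spectra$frequencies,
                     spectra$Gpv / spectra$Gvv,
                     pmin(pmax(coh, 0), 1),
                     n_exams = 1L)
}

#' Estimate an impedance spectrum from one exam
#'
#' Convenience wrapper: [estimate_spectra] then [impedance_from_spectra].
#'
#' @inheritParams estimate_spectra
#' @return An [impedance_spectrum].
#' @export
estimate_impedance <- function(exam, grid = seq(2, 32, by = 2),
                               segment_duration = 4, overlap = 0.5) {
  impedance_from_spectra(estimate_spectra(exam, grid, segment_duration, overlap))
}

#' Coherence-based exam quality gate
#'
#' An exam is retained only when the squared coherence reaches the threshold
#' at every grid frequency in the analysis band. The default band starts at
#' 4 Hz: the 2 Hz line, closest to the breathing fundamental, is kept in the
#' spectrum but exempt from the gate because no downstream index uses it.
#'
#' @param spectrum An [impedance_spectrum].
#' @param threshold Minimum acceptable coherence, in (0, 1\]; default 0.9.
#' @param band Analysis band (Hz) over which the gate applies.
#' @return `TRUE` if the exam passes.
#' @export
accept_exam <- function(spectrum, threshold = 0.9, band = c(4, 32)) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    stopf("threshold must lie in (0, 1]")
  }
  idx <- band_index(spectrum, band)
  all(spectrum$coherence[idx] >= threshold)
}

#' Average accepted exams into a final spectrum
#'
#' Per-frequency arithmetic mean of the complex impedance across exams; the
#' reported coherence is the per-frequency minimum (conservative), and
#' `n_exams` records how many exams went in.
#'
#' @param spectra List of [impedance_spectrum] objects on identical grids.
#' @return An [impedance_spectrum].
#' @export
average_exams <- function(spectra) {
  if (length(spectra) < 1L) stopf("need at least one accepted spectrum")
  ref <- spectra[[1]]
  for (s in spectra[-1]) check_same_grid(ref, s)
  vals <- Reduce(`+`, lapply(spectra, `[[`, "values")) / length(spectra)
  coh <- do.call(pmin, lapply(spectra, `[[`, "coherence"))
  impedance_spectrum(ref$frequencies, vals, coh, n_exams = length(spectra))
}

#' Final averaged spectrum for a virtual subject
#'
#' Estimates the impedance of each of the subject's exams, applies the
#' coherence gate, and averages the satisfactory exams.
#'
#' @param subject A `virtual_subject`.
#' @param grid Analysis grid (Hz).
#' @param threshold Coherence gate level.
#' @param band Gate band (Hz).
#' @param ... Passed to [estimate_spectra].
#' @return An [impedance_spectrum].
#' @export
subject_spectrum <- function(subject, grid = seq(2, 32, by = 2),
                             threshold = 0.9, band = c(4, 32), ...) {
  stopifnot(inherits(subject, "virtual_subject"))
  specs <- lapply(subject$exams, estimate_impedance, grid = grid, ...)
  ok <- vapply(specs, accept_exam, logical(1),
               threshold = threshold, band = band)
  if (!any(ok)) {
    stopf("no exam of subject (seed %d) passed the coherence gate at %.2g",
          subject$seed, threshold)
  }
  average_exams(specs[ok])
}
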