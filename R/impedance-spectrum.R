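#' Respiratory impedance spectrum
#'
#' Container for a complex respiratory impedance \eqn{Z_{rs}(f)} on an
#' ascending frequency grid, together with the per-frequency coherence
#' \eqn{\gamma^2} used for exam quality control and the number of exams
#' averaged into it.
#'
#' @param frequencies Numeric vector of strictly increasing frequencies (Hz).
#' @param values Complex vector of impedance values (cmH2O/L/s), one per
#'   frequency.
#' @param coherence Numeric vector of squared coherence values in \[0, 1\].
#'   Defaults to 1 at every line (an analytic, noise-free spectrum).
#' @param n_exams Integer count of exams averaged into this spectrum.
#'
#' @return An object of class `impedance_spectrum`: a list with fields
#'   `frequencies`, `values`, `coherence`, `n_exams`.
#' @export
#' @examples
#' z <- impedance_spectrum(c(4, 8, 16), complex(real = 3:1, imaginary = -1))
impedance_spectrum <- function(frequencies, values,
                               coherence = rep(1, length(frequencies)),
                               n_exams = 1L) {
  frequencies <- as.numeric(frequencies)
  values <- as.complex(values)
  coherence <- as.numeric(coherence)
  if (length(frequencies) < 1L) stopf("empty frequency grid")
  if (any(!is.finite(frequencies)) || any(diff(frequencies) <= 0)) {
    stopf("frequencies must be finite and strictly increasing")
  }
  if (length(values) != length(frequencies)) {
    stopf("values and frequencies differ in length")
  }
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stopf("impedance values must be finite")
  }
  if (length(coherence) != length(frequencies) ||
      any(!is.finite(coherence)) ||
      any(coherence < 0 | coherence > 1)) {
    stopf("coherence must lie in [0, 1] at every grid frequency")
  }
  structure(
    list(frequencies = frequencies, values = values,
         coherence = coherence, n_exams = as.integer(n_exams)),
    class = "impedance_spectrum"
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<impedance_spectrum> %d lines, %.3g-%.3g Hz, min coherence %.4f, %d exam(s)\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    min(x$coherence), x$n_exams))
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies,
             resistance = Re(x$values),
             reactance = Im(x$values),
             coherence = x$coherence)
}

# Subset of grid indices lying inside a [lo, hi] band (inclusive).
band_index <- function(spectrum, band) {
  which(spectrum$frequencies >= band[1] - 1e-9 &
          spectrum$frequencies <= band[2] + 1e-9)
}

check_same_grid <- function(a, b) {
  if (length(a$frequencies) != length(b$frequencies) ||
      any(abs(a$frequencies - b$frequencies) > 1e-9)) {
    stopf("frequency grids do not match")
  }
  invisible(TRUE)
}
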