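#' Intercept resistance and resistance slope (R0, S)
#'
#' Ordinary least squares of the resistance (real part of the impedance) on
#' frequency over the 4-16 Hz grid points. The intercept R0 extrapolates the
#' Newtonian plus gas-redistribution resistance to 0 Hz; a negative slope S
#' reflects ventilatory non-homogeneity.
#'
#' @param spectrum An [impedance_spectrum] whose grid contains 4, 6, ..., 16 Hz.
#' @param band Regression band (Hz), default `c(4, 16)`.
#' @return Named numeric vector `c(R0, S)` (cmH2O/L/s and cmH2O/L/s per Hz).
#' @export
resistance_regression <- function(spectrum, band = c(4, 16)) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  want <- seq(band[1], band[2], by = 2)
  idx <- match(want, round(spectrum$frequencies, 6))
  if (anyNA(idx)) {
    stopf("grid is missing regression frequencies: %s Hz",
          paste(want[is.na(idx)], collapse = ", "))
  }
  fit <- stats::lm(re ~ f,
                   data = data.frame(f = spectrum$frequencies[idx],
                                     re = Re(spectrum$values[idx])))
  c(R0 = unname(stats::coef(fit)[1]), S = unname(stats::coef(fit)[2]))
}

#' Resonant frequency
#'
#' The lowest frequency in the analysis band at which the reactance crosses
#' zero from negative to positive, located by linear interpolation between
#' the bracketing grid points (or snapped to the upper grid point with
#' `interpolate = FALSE`). Absence of a crossing is a value, not an error:
#' `NA_real_` is returned.
#'
#' @param spectrum An [impedance_spectrum].
#' @param band Search band (Hz), default 4-32.
#' @param interpolate Linear interpolation between grid points (default) or
#'   grid snapping.
#' @return Resonant frequency (Hz) or `NA_real_`.
#' @export
resonant_frequency <- function(spectrum, band = c(4, 32), interpolate = TRUE) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  idx <- band_index(spectrum, band)
  f <- spectrum$frequencies[idx]
  x <- Im(spectrum$values[idx])
  for (k in seq_len(length(f) - 1L)) {
    if (x[k] < 0 && x[k + 1L] >= 0) {
      if (!interpolate || x[k + 1L] == x[k]) return(f[k + 1L])
      return(f[k] + (0 - x[k]) * (f[k + 1L] - f[k]) / (x[k + 1L] - x[k]))
    }
  }
  NA_real_
}

#' Mean reactance and reactance area (Xm, Ax)
#'
#' `Xm` is the arithmetic mean of the reactance over the 4-32 Hz grid
#' points. `Ax` is the trapezoidal integral over the band of the negative
#' part of the reactance curve, `max(0, -X)`, so it is zero when the
#' reactance is nonnegative everywhere and grows as the curve dips further
#' below zero.
#'
#' @param spectrum An [impedance_spectrum].
#' @param band Band (Hz), default 4-32.
#' @return Named numeric vector `c(Xm, Ax)` (cmH2O/L/s and cmH2O/L).
#' @export
reactance_summaries <- function(spectrum, band = c(4, 32)) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  idx <- band_index(spectrum, band)
  f <- spectrum$frequencies[idx]
  x <- Im(spectrum$values[idx])
  c(Xm = mean(x), Ax = pracma::trapz(f, pmax(0, -x)))
}

#' Point indices at 4 Hz (R4, Cdyn, Zrs4)
#'
#' `R4` is the resistance at 4 Hz and `Zrs4` the impedance modulus there,
#' a proxy for the work of breathing. Dynamic compliance is estimated from
#' the 4 Hz reactance as \eqn{C_{dyn} = -1/(2\pi f X_{4Hz})}; when the
#' reactance at 4 Hz is nonnegative the elastic reading is undefined and
#' `Cdyn` is `NA` with a warning.
#'
#' @param spectrum An [impedance_spectrum] with 4 Hz on its grid.
#' @return Named numeric vector `c(R4, Cdyn, Zrs4)`.
#' @export
point_indices <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  k <- match(4, round(spectrum$frequencies, 6))
  if (is.na(k)) stopf("grid does not contain 4 Hz")
  z4 <- spectrum$values[k]
  x4 <- Im(z4)
  cdyn <- if (x4 < 0) -1 / (2 * pi * 4 * x4) else {
    warning("reactance at 4 Hz is nonnegative; Cdyn undefined", call. = FALSE)
    NA_real_
  }
  c(R4 = Re(z4), Cdyn = cdyn, Zrs4 = Mod(z4))
}

#' All eight FOT indices of a spectrum
#'
#' Computes the resistive indices (R0, S from the 4-16 Hz regression, R4),
#' the reactive indices (fr, Xm, Ax) and the 4 Hz point readings (Cdyn,
#' Zrs4) from one averaged impedance spectrum.
#'
#' @param spectrum An [impedance_spectrum].
#' @param reactance_band Band for fr, Xm, Ax (Hz).
#' @param regression_band Band for R0, S (Hz).
#' @return Object of class `fot_indices`: a named list with entries
#'   `R0, S, R4, fr, Xm, Ax, Cdyn, Zrs4`.
#' @export
#' @examples
#' sp <- eric_impedance(eric_params(1.5, 3.0, 0.008, 0.01), seq(2, 32, 2))
#' unlist(fot_indices(sp))
fot_indices <- function(spectrum, reactance_band = c(4, 32),
                        regression_band = c(4, 16)) {
  rs <- resistance_regression(spectrum, regression_band)
  xs <- reactance_summaries(spectrum, reactance_band)
  pt <- point_indices(spectrum)
  structure(
    list(R0 = rs[["R0"]], S = rs[["S"]], R4 = pt[["R4"]],
         fr = resonant_frequency(spectrum, reactance_band),
         Xm = xs[["Xm"]], Ax = xs[["Ax"]],
         Cdyn = pt[["Cdyn"]], Zrs4 = pt[["Zrs4"]]),
    class = "fot_indices")
}

#' @export
print.fot_indices <- function(x, ...) {
  cat("<fot_indices>\n")
  print(round(unlist(x), 4))
  invisible(x)
}

#' @export
as.data.frame.fot_indices <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
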