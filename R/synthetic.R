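#' Cohort profile for virtual FOT subjects
#'
#' A profile bundles the stochastic law generating eRIC loads for a cohort
#' with the acquisition conditions of a pseudorandom-noise FOT exam:
#' multisine pressure excitation of about 1 cmH2O peak on the 2-32 Hz grid,
#' spontaneous-breathing interference near 0.2 Hz on the flow channel, and
#' white measurement noise on both channels.
#'
#' Each circuit element follows an independent log-normal law, parameterized
#' by its median and log-scale (`sdlog`); a zero `sdlog` pins the element at
#' its median.
#'
#' @param name Profile label (e.g. `"control"`, `"cf"`).
#' @param param_law Named list with entries `R`, `Rp`, `I`, `C`, each a list
#'   (or named vector) with `median` and `sdlog`.
#' @param excitation_amplitude Peak excitation pressure (cmH2O).
#' @param breathing_frequency Spontaneous breathing rate (Hz), in (0.05, 0.5).
#' @param breathing_flow_amplitude Peak breathing flow (L/s) superimposed on
#'   the flow channel (first harmonic added at 30 percent amplitude).
#' @param pressure_noise_sd,flow_noise_sd White measurement noise SD per
#'   channel (cmH2O and L/s).
#' @param r0_target Optional list/vector with `mean` and `sd`: population
#'   moments of the intercept resistance R0 that [calibrate_profile] should
#'   reproduce.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(name, param_law,
                            excitation_amplitude = 1,
                            breathing_frequency = 0.2,
                            breathing_flow_amplitude = 0.3,
                            pressure_noise_sd = 0.02,
                            flow_noise_sd = 0.005,
                            r0_target = NULL) {
  elems <- c("R", "Rp", "I", "C")
  if (!is.list(param_law) || !all(elems %in% names(param_law))) {
    stopf("param_law must name laws for all of R, Rp, I, C")
  }
  law <- lapply(param_law[elems], function(x) {
    x <- as.list(x)
    med <- as.numeric(x$median); sdl <- as.numeric(x$sdlog)
    if (!is_scalar_number(med) || med <= 0) stopf("law median must be positive")
    list(median = med, sdlog = sdl)
  })
  for (nm in elems) {
    sdl <- law[[nm]]$sdlog
    if (!is_scalar_number(sdl) || sdl < 0) {
      stopf("invalid profile: nonpositive-definite scale for element '%s'", nm)
    }
  }
  if (!is_scalar_number(excitation_amplitude) || excitation_amplitude <= 0) {
    stopf("excitation_amplitude must be positive")
  }
  if (breathing_frequency <= 0.05 || breathing_frequency >= 0.5) {
    stopf("breathing_frequency must lie in (0.05, 0.5) Hz")
  }
  if (breathing_flow_amplitude < 0 || pressure_noise_sd < 0 || flow_noise_sd < 0) {
    stopf("noise and breathing amplitudes must be nonnegative")
  }
  if (!is.null(r0_target)) {
    r0_target <- as.list(r0_target)
    if (!is_scalar_number(r0_target$mean) || r0_target$mean <= 0 ||
        !is_scalar_number(r0_target$sd) || r0_target$sd <= 0) {
      stopf("r0_target must give positive mean and sd")
    }
  }
  structure(
    list(name = as.character(name), param_law = law,
         excitation_amplitude = excitation_amplitude,
         breathing_frequency = breathing_frequency,
         breathing_flow_amplitude = breathing_flow_amplitude,
         pressure_noise_sd = pressure_noise_sd,
         flow_noise_sd = flow_noise_sd,
         r0_target = r0_target),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> '%s'\n", x$name))
  for (nm in names(x$param_law)) {
    cat(sprintf("  %-2s ~ logN(median %.4g, sdlog %.3g)\n",
                nm, x$param_law[[nm]]$median, x$param_law[[nm]]$sdlog))
  }
  cat(sprintf("  excitation %.3g cmH2O peak; breathing %.3g Hz x %.3g L/s; noise sd %.3g / %.3g\n",
              x$excitation_amplitude, x$breathing_frequency,
              x$breathing_flow_amplitude, x$pressure_noise_sd, x$flow_noise_sd))
  invisible(x)
}

#' Built-in cohort profiles
#'
#' Loads the packaged `control` and `cf` (cystic fibrosis) profiles. The CF
#' profile ships with population R0 targets (mean 4.71, SD 1.52 cmH2O/L/s);
#' with `calibrate = TRUE` (default) its central-resistance law is adjusted
#' by [calibrate_profile] so that the implied R0 distribution matches them.
#'
#' @param name `"control"` or `"cf"`, or a path to a YAML profile file.
#' @param calibrate Apply [calibrate_profile] when the profile carries an
#'   `r0_target`.
#' @return A [subject_profile].
#' @export
#' @examples
#' fot_profile("control")
fot_profile <- function(name = c("control", "cf"), calibrate = TRUE) {
  if (file.exists(name[1]) && grepl("\\.ya?ml$", name[1])) {
    defs <- yaml::read_yaml(name[1])
    key <- names(defs)[1]
  } else {
    name <- match.arg(name)
    defs <- yaml::read_yaml(system.file("extdata", "profiles.yaml",
                                        package = "ericfot", mustWork = TRUE))
    key <- name
    if (!key %in% names(defs)) stopf("no packaged profile named '%s'", key)
  }
  d <- defs[[key]]
  prof <- subject_profile(
    name = key, param_law = d$param_law,
    excitation_amplitude = d$excitation_amplitude %||% 1,
    breathing_frequency = d$breathing_frequency %||% 0.2,
    breathing_flow_amplitude = d$breathing_flow_amplitude %||% 0.3,
    pressure_noise_sd = d$pressure_noise_sd %||% 0.02,
    flow_noise_sd = d$flow_noise_sd %||% 0.005,
    r0_target = d$r0_target)
  if (calibrate && !is.null(prof$r0_target)) {
    prof <- calibrate_profile(prof, prof$r0_target$mean, prof$r0_target$sd)
  }
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_law <- function(law, n) {
  if (law$sdlog == 0) rep(law$median, n)
  else stats::rlnorm(n, meanlog = log(law$median), sdlog = law$sdlog)
}

#' Draw a virtual subject
#'
#' Draws an eRIC truth from the profile's parameter law and synthesizes the
#' three repeated FOT exams of a standard session. Deterministic given
#' `(profile, seed)`.
#'
#' @param profile A [subject_profile].
#' @param seed Integer seed for this subject.
#' @param n_exams Number of repeated exams (default 3).
#' @param sampling_rate,duration Acquisition settings passed to
#'   [synthesize_exam].
#' @param grid Excitation grid (Hz).
#' @return An object of class `virtual_subject` with fields `truth`
#'   ([eric_params]), `profile_name`, `seed`, `exams` (list of
#'   `exam_record`).
#' @export
draw_subject <- function(profile, seed, n_exams = 3L,
                         sampling_rate = 256, duration = 16,
                         grid = seq(2, 32, by = 2)) {
  stopifnot(inherits(profile, "subject_profile"))
  truth <- with_seed(seed, {
    eric_params(R = draw_law(profile$param_law$R, 1),
                Rp = draw_law(profile$param_law$Rp, 1),
                I = draw_law(profile$param_law$I, 1),
                C = draw_law(profile$param_law$C, 1))
  })
  exam_seeds <- derive_seeds(seed + 1L, n_exams)
  exams <- lapply(exam_seeds, function(s) {
    synthesize_exam(truth, profile, s, sampling_rate = sampling_rate,
                    duration = duration, grid = grid)
  })
  structure(
    list(truth = truth, profile_name = profile$name,
         seed = as.integer(seed), exams = exams),
    class = "virtual_subject")
}

#' One synthetic FOT exam record
#'
#' Constructor for a paired pressure/flow acquisition at a fixed sampling
#' interval.
#'
#' @param pressure Pressure samples (cmH2O).
#' @param flow Flow samples (L/s).
#' @param sampling_interval Sampling interval (s).
#' @return An object of class `exam_record`.
#' @export
exam_record <- function(pressure, flow, sampling_interval) {
  if (length(pressure) != length(flow)) stopf("pressure and flow differ in length")
  if (!is_scalar_number(sampling_interval) || sampling_interval <= 0) {
    stopf("sampling_interval must be a positive scalar")
  }
  structure(
    list(pressure = as.numeric(pressure), flow = as.numeric(flow),
         sampling_interval = sampling_interval,
         duration = length(pressure) * sampling_interval),
    class = "exam_record")
}

#' @export
print.exam_record <- function(x, ...) {
  cat(sprintf("<exam_record> %.4g s at %.4g Hz (%d samples)\n",
              x$duration, 1 / x$sampling_interval, length(x$pressure)))
  invisible(x)
}

#' Synthesize a pseudorandom-noise FOT exam from an eRIC load
#'
#' The excitation is a multisine: equal-amplitude cosines at the grid
#' frequencies with seed-determined uniform phases, rescaled so the peak
#' pressure equals the profile amplitude. The flow response is built line by
#' line through the load's admittance \eqn{1/Z(f)} (exact for a periodic
#' multisine), then a spontaneous-breathing flow component (fundamental plus
#' a 30 percent first harmonic) and independent white Gaussian noise on both
#' channels are added. With all noise and breathing amplitudes at zero the
#' pressure-to-flow transfer equals \eqn{1/Z} exactly at every grid line.
#'
#' @param truth An [eric_params] load.
#' @param profile A [subject_profile] providing amplitudes and noise levels.
#' @param seed Integer seed.
#' @param sampling_rate Samples per second (Hz); must be at least four times
#'   the highest grid frequency.
#' @param duration Exam length (s).
#' @param grid Excitation frequencies (Hz).
#' @return An `exam_record`.
#' @export
synthesize_exam <- function(truth, profile, seed,
                            sampling_rate = 256, duration = 16,
                            grid = seq(2, 32, by = 2)) {
  stopifnot(inherits(truth, "eric_params"), inherits(profile, "subject_profile"))
  if (sampling_rate < 4 * max(grid)) {
    stopf("sampling rate %.3g Hz is below the 4x Nyquist margin for %.3g Hz",
          sampling_rate, max(grid))
  }
  n <- round(sampling_rate * duration)
  t <- (seq_len(n) - 1) / sampling_rate
  z <- eric_z(truth$R, truth$Rp, truth$I, truth$C, grid)

  with_seed(seed, {
    phases <- stats::runif(length(grid), 0, 2 * pi)
    arg <- outer(2 * pi * grid, t) + phases             # lines x samples
    p_exc <- colSums(cos(arg))
    scale <- profile$excitation_amplitude / max(abs(p_exc))
    v_exc <- colSums(cos(arg - Arg(z)) / Mod(z)) * scale
    p_exc <- p_exc * scale

    fb <- profile$breathing_frequency
    ab <- profile$breathing_flow_amplitude
    ph_b <- stats::runif(2, 0, 2 * pi)
    v_breath <- ab * sin(2 * pi * fb * t + ph_b[1]) +
      0.3 * ab * sin(2 * pi * 2 * fb * t + ph_b[2])

    pressure <- p_exc + stats::rnorm(n, 0, profile$pressure_noise_sd)
    flow <- v_exc + v_breath + stats::rnorm(n, 0, profile$flow_noise_sd)
    exam_record(pressure, flow, 1 / sampling_rate)
  })
}

#' Generate a cohort of virtual subjects
#'
#' Subject seeds are derived reproducibly from the master seed, so the whole
#' cohort is a pure function of `(profile, n, seed)`.
#'
#' @param profile A [subject_profile].
#' @param n Number of subjects (the study cohorts are 23 controls and 27 CF).
#' @param seed Master seed.
#' @param ... Passed to [draw_subject].
#' @return List of `virtual_subject` objects.
#' @export
generate_cohort <- function(profile, n, seed, ...) {
  if (!is_scalar_number(n) || n < 1) stopf("cohort size n must be at least 1")
  subject_seeds <- derive_seeds(seed, n)
  lapply(subject_seeds, function(s) draw_subject(profile, s, ...))
}

# OLS intercept weights for the R0 regression band (resistance on frequency,
# 4-16 Hz): R0 = w . Re Z(f). Since sum(w) = 1 and the R element shifts
# Re Z uniformly, R0 = R + w . g(f; Rp, C) with g the parallel-branch
# resistance -- the basis of the analytic calibration below.
r0_intercept_weights <- function(freqs = seq(4, 16, by = 2)) {
  X <- cbind(1, freqs)
  drop(solve(crossprod(X), t(X))[1, ])
}

# Analytic R0 for given parallel-branch draws (vectors Rp, C) plus central R.
implied_r0_values <- function(R, Rp, C, freqs = seq(4, 16, by = 2)) {
  w <- r0_intercept_weights(freqs)
  g <- vapply(seq_along(freqs), function(k) {
    om <- 2 * pi * freqs[k]
    Rp / (1 + (om * Rp * C)^2)
  }, numeric(length(Rp)))
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  R + drop(g %*% w)
}

#' Population moments of the intercept resistance implied by a profile
#'
#' Monte-Carlo estimate (analytic per draw: the regression of the eRIC
#' resistance over 4-16 Hz has a closed form once the circuit elements are
#' drawn) of the mean and SD of R0 under a profile's parameter law.
#'
#' @param profile A [subject_profile].
#' @param n_draws Monte-Carlo size.
#' @param seed Seed for the estimate (fixed default keeps it reproducible).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
implied_r0_moments <- function(profile, n_draws = 20000L, seed = 760417L) {
  stopifnot(inherits(profile, "subject_profile"))
  r0 <- with_seed(seed, {
    implied_r0_values(draw_law(profile$param_law$R, n_draws),
                      draw_law(profile$param_law$Rp, n_draws),
                      draw_law(profile$param_law$C, n_draws))
  })
  c(mean = mean(r0), sd = stats::sd(r0))
}

#' Calibrate a profile's central-resistance law to target R0 moments
#'
#' Adjusts only the log-normal law of the central resistance R so that the
#' population mean and SD of the regression-derived intercept resistance R0
#' match the targets; the Rp, I and C laws are untouched. Because R enters
#' R0 additively and independently of the parallel branch, the required R
#' moments are `mean(R) = target_mean - mean(G)` and
#' `var(R) = target_sd^2 - var(G)`, with G the parallel-branch intercept
#' contribution, estimated by a fixed-seed Monte Carlo; the log-normal law
#' matching those two moments is then exact.
#'
#' @param profile A [subject_profile].
#' @param target_mean_r0,target_sd_r0 Target population moments of R0
#'   (cmH2O/L/s).
#' @param n_draws Monte-Carlo size for the parallel-branch moments.
#' @return The calibrated [subject_profile].
#' @export
#' @examples
#' calibrate_profile(fot_profile("cf", calibrate = FALSE), 4.71, 1.52)
calibrate_profile <- function(profile, target_mean_r0, target_sd_r0,
                              n_draws = 20000L) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is_scalar_number(target_mean_r0) || target_mean_r0 <= 0 ||
      !is_scalar_number(target_sd_r0) || target_sd_r0 <= 0) {
    stopf("calibration targets must be positive")
  }
  g <- with_seed(760418L, {
    implied_r0_values(0, draw_law(profile$param_law$Rp, n_draws),
                      draw_law(profile$param_law$C, n_draws))
  })
  mean_g <- mean(g); var_g <- stats::var(g)
  mean_r <- target_mean_r0 - mean_g
  if (mean_r <= 0) {
    stopf(paste0("target mean R0 (%.3g) is below the peripheral-branch ",
                 "contribution (%.3g); unreachable with positive R"),
          target_mean_r0, mean_g)
  }
  var_r <- target_sd_r0^2 - var_g
  if (var_r <= 0) {
    stopf(paste0("target SD of R0 (%.3g) is below the spread already induced ",
                 "by the Rp and C laws (%.3g); unreachable"),
          target_sd_r0, sqrt(var_g))
  }
  sdlog2 <- log(1 + var_r / mean_r^2)
  meanlog <- log(mean_r) - sdlog2 / 2
  out <- profile
  out$param_law$R <- list(median = unname(exp(meanlog)),
                          sdlog = unname(sqrt(sdlog2)))
  out
}
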