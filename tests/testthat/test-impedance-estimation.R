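test_that("an identity channel yields real-positive Gpv and unit coherence", {
  set.seed(41)
  x <- rnorm(4096)
  ex <- exam_record(pressure = x, flow = x, sampling_interval = 1 / 256)
  cs <- estimate_spectra(ex)
  expect_true(all(Re(cs$Gpv) > 0))
  expect_lt(max(abs(Im(cs$Gpv))), 1e-12)
  expect_equal(cs$segment_count, 7L)
  z <- impedance_from_spectra(cs)
  expect_equal(z$values, rep(1 + 0i, 16), tolerance = 1e-9)
  expect_equal(z$coherence, rep(1, 16), tolerance = 1e-9)
})

test_that("impedance and coherence are invariant to channel scaling", {
  truth <- example_truth()
  ex <- synthesize_exam(truth, fot_profile("control"), seed = 17)
  ex2 <- exam_record(3.7 * ex$pressure, 3.7 * ex$flow, ex$sampling_interval)
  z1 <- estimate_impedance(ex)
  z2 <- estimate_impedance(ex2)
  expect_equal(z1$values, z2$values, tolerance = 1e-12)
  expect_equal(z1$coherence, z2$coherence, tolerance = 1e-12)
})

test_that("noiseless exams reproduce the analytic impedance and unit coherence", {
  truth <- example_truth()
  ex <- synthesize_exam(truth, quiet_profile(), seed = 23)
  z <- estimate_impedance(ex)
  za <- eric_impedance(truth, z$frequencies)$values
  expect_lt(max(Mod(z$values - za) / Mod(za)), 1e-3)
  expect_true(all(z$coherence > 1 - 1e-9))
})

test_that("independent white-noise channels give low coherence", {
  set.seed(59)
  ex <- exam_record(rnorm(4096), rnorm(4096), 1 / 256)
  z <- estimate_impedance(ex)
  expect_lt(mean(z$coherence), 0.5)
})

test_that("coherence respects its bounds on arbitrary random exams", {
  set.seed(61)
  for (k in 1:10) {
    mix <- runif(1)
    common <- rnorm(4096)
    ex <- exam_record(common + mix * rnorm(4096),
                      0.5 * common + mix * rnorm(4096), 1 / 256)
    z <- estimate_impedance(ex)
    expect_true(all(z$coherence >= 0 & z$coherence <= 1))
  }
})

test_that("the coherence gate applies per frequency over the analysis band", {
  grid <- default_grid()
  vals <- eric_impedance(example_truth(), grid)$values
  all_good <- impedance_spectrum(grid, vals, rep(1, 16))
  expect_true(accept_exam(all_good))
  coh <- rep(0.95, 16); coh[grid == 20] <- 0.89
  expect_false(accept_exam(impedance_spectrum(grid, vals, coh)))
  # the 2 Hz line is exempt: it is outside the analyzed band
  coh2 <- rep(0.95, 16); coh2[grid == 2] <- 0.3
  expect_true(accept_exam(impedance_spectrum(grid, vals, coh2)))
  expect_true(accept_exam(impedance_spectrum(grid, vals, rep(0.01, 16)),
                          threshold = 0.005))
  expect_error(accept_exam(all_good, threshold = 1.01), "threshold")
})

test_that("exam averaging is idempotent, linear and records exam counts", {
  grid <- default_grid()
  z <- impedance_spectrum(grid, eric_impedance(example_truth(), grid)$values,
                          rep(0.97, 16))
  avg <- average_exams(list(z, z, z))
  expect_equal(avg$values, z$values)
  expect_equal(avg$coherence, z$coherence)
  expect_identical(avg$n_exams, 3L)
  minus <- impedance_spectrum(grid, -z$values, rep(0.95, 16))
  zero <- impedance_spectrum(grid, rep(0 + 0i, 16), rep(1, 16))
  cancel <- average_exams(list(z, minus, zero))
  expect_equal(Mod(cancel$values), rep(0, 16))
  expect_equal(cancel$coherence, rep(0.95, 16))  # conservative minimum
  other <- impedance_spectrum(grid + 1, z$values)
  expect_error(average_exams(list(z, other)), "grids")
})

test_that("averaging three noisy exams beats a typical single exam", {
  set.seed(73)
  truth <- example_truth()
  za <- eric_impedance(truth, default_grid())$values
  wins <- replicate(100, {
    reps <- lapply(1:3, function(i) noisy_spectrum(truth, sd = 0.1))
    davg <- sqrt(sum(Mod(average_exams(reps)$values - za)^2))
    dsingle <- vapply(reps, function(s) sqrt(sum(Mod(s$values - za)^2)),
                      numeric(1))
    davg < stats::median(dsingle)
  })
  expect_gt(mean(wins), 0.8)
})

test_that("estimation rejects unusable inputs by name", {
  ex <- exam_record(rnorm(512), rnorm(512), 1 / 256)
  expect_error(estimate_spectra(ex), "2 averaging segments")
  ex2 <- exam_record(rnorm(4096), rnorm(4096), 1 / 256)
  expect_error(estimate_spectra(ex2, grid = c(0.1, 4)), "0.1")
  expect_error(estimate_spectra(ex2, grid = c(4, 200)), "200")
  cs <- estimate_spectra(ex2)
  cs$Gvv[3] <- 0
  expect_error(impedance_from_spectra(cs), "degenerate excitation")
})

test_that("a subject's averaged spectrum uses only gate-passing exams", {
  subj <- draw_subject(fot_profile("control"), seed = 99)
  sp <- subject_spectrum(subj)
  expect_gte(sp$n_exams, 1L)
  expect_lte(sp$n_exams, 3L)
  expect_true(all(sp$coherence[sp$frequencies >= 4] >= 0.9))
})
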