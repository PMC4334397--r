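spec_from_parts <- function(re, im, grid = default_grid()) {
  impedance_spectrum(grid, complex(real = re, imaginary = im))
}

test_that("the resistance regression reproduces known lines", {
  grid <- default_grid()
  flat <- spec_from_parts(rep(3, 16), rep(-0.5, 16))
  expect_equal(resistance_regression(flat), c(R0 = 3, S = 0))
  line <- spec_from_parts(5 - 0.1 * grid, rep(-0.5, 16))
  expect_equal(resistance_regression(line), c(R0 = 5, S = -0.1))
  short <- impedance_spectrum(seq(6, 32, 2), rep(1 + 0i, 14))
  expect_error(resistance_regression(short), "4")
})

test_that("the regression agrees with an independent normal-equations solve", {
  sp <- eric_impedance(example_truth(), default_grid())
  f <- seq(4, 16, 2)
  re <- Re(sp$values[match(f, sp$frequencies)])
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% re)   # brute-force least squares
  got <- resistance_regression(sp)
  expect_equal(unname(got["R0"]), beta[1], tolerance = 1e-10)
  expect_equal(unname(got["S"]), beta[2], tolerance = 1e-10)
})

test_that("resonant frequency interpolates the first negative-to-positive crossing", {
  grid <- default_grid()
  # series R-I-C with I = C = 0.01: analytic zero at 1/(2*pi*0.01) = 15.915 Hz
  x_ric <- 2 * pi * grid * 0.01 - 1 / (2 * pi * grid * 0.01)
  sp <- spec_from_parts(rep(2, 16), x_ric)
  expect_equal(resonant_frequency(sp), 1 / (2 * pi * 0.01), tolerance = 0.02)
  expect_true(is.na(resonant_frequency(spec_from_parts(rep(2, 16), rep(-1, 16)))))
  # grid snapping lands on the upper bracketing point
  expect_equal(resonant_frequency(sp, interpolate = FALSE), 16)
  # exact for a linear reactance crossing between grid points
  sp_lin <- spec_from_parts(rep(2, 16), grid - 15)
  expect_equal(resonant_frequency(sp_lin), 15)
})

test_that("eRIC spectra resonate where the closed form says", {
  set.seed(404)
  for (k in 1:50) {
    p <- random_eric_params()
    fr_true <- eric_resonant_frequency(p)
    fr_est <- resonant_frequency(eric_impedance(p, default_grid()))
    if (is.na(fr_true) || fr_true <= 4 || fr_true > 32) {
      expect_true(is.na(fr_est) || fr_est <= 4.5)
    } else {
      expect_equal(fr_est, fr_true, tolerance = 0.05)  # interpolation step
    }
  }
})

test_that("mean reactance and reactance area match hand-computed values", {
  grid <- default_grid()
  const <- spec_from_parts(rep(2, 16), rep(-1, 16))
  expect_equal(reactance_summaries(const), c(Xm = -1, Ax = 28))
  pos <- spec_from_parts(rep(2, 16), rep(0.4, 16))
  expect_equal(unname(reactance_summaries(pos)["Ax"]), 0)
  # linear reactance f - 16: grid mean 2; triangle below zero has area 72
  lin <- spec_from_parts(rep(2, 16), grid - 16)
  expect_equal(reactance_summaries(lin), c(Xm = 2, Ax = 72))
})

test_that("reactance area grows when the curve dips further below zero", {
  grid <- default_grid()
  x <- grid - 16
  base <- reactance_summaries(spec_from_parts(rep(2, 16), x))["Ax"]
  x2 <- x; x2[x2 < 0] <- x2[x2 < 0] - 0.5
  deeper <- reactance_summaries(spec_from_parts(rep(2, 16), x2))["Ax"]
  expect_gt(deeper, base)
})

test_that("4 Hz point indices follow their defining identities", {
  grid <- default_grid()
  im <- rep(-1, 16); im[grid == 4] <- -1 / (8 * pi)
  sp <- spec_from_parts(rep(2, 16), im)
  expect_equal(unname(point_indices(sp)["Cdyn"]), 1, tolerance = 1e-12)
  re <- rep(2, 16); re[grid == 4] <- 3
  im2 <- rep(-1, 16); im2[grid == 4] <- -4
  pt <- point_indices(spec_from_parts(re, im2))
  expect_equal(unname(pt["R4"]), 3)
  expect_equal(unname(pt["Zrs4"]), 5)
  expect_equal(unname(pt["Cdyn"]), 1 / (32 * pi), tolerance = 1e-12)
  im3 <- rep(-1, 16); im3[grid == 4] <- 0.5
  expect_warning(pt3 <- point_indices(spec_from_parts(re, im3)), "Cdyn")
  expect_true(is.na(pt3["Cdyn"]))
})

test_that("the Cdyn inversion identity holds on random spectra", {
  set.seed(505)
  for (k in 1:30) {
    sp <- noisy_spectrum(random_eric_params(), sd = 0.2)
    pt <- suppressWarnings(point_indices(sp))
    x4 <- Im(sp$values[sp$frequencies == 4])
    if (!is.na(pt["Cdyn"])) {
      expect_equal(unname(pt["Cdyn"]) * 8 * pi * (-x4), 1, tolerance = 1e-12)
      expect_gt(pt["Cdyn"], 0)
    }
    expect_gte(unname(pt["Zrs4"]), abs(unname(pt["R4"])))
  }
})

test_that("the eight indices assemble into one record", {
  idx <- fot_indices(eric_impedance(example_truth(), default_grid()))
  expect_named(unclass(idx),
               c("R0", "S", "R4", "fr", "Xm", "Ax", "Cdyn", "Zrs4"))
  expect_equal(idx$R4, 3.412669, tolerance = 1e-5)
  expect_equal(idx$fr, eric_resonant_frequency(example_truth()),
               tolerance = 0.05)
  expect_gt(idx$Ax, 0)
  df <- as.data.frame(idx)
  expect_identical(dim(df), c(1L, 8L))
})
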