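two_group_table <- function(a, b) {
  data.frame(group = rep(c("control", "cf"), c(length(a), length(b))),
             v = c(a, b))
}

test_that("correlation bands honor their boundaries exactly", {
  expect_identical(correlation_band(c(0, 0.25, -0.25)), rep("small-or-none", 3))
  expect_identical(correlation_band(c(0.2500001, 0.5, -0.4)),
                   rep("reasonable", 3))
  expect_identical(correlation_band(c(0.5000001, 0.75)),
                   rep("moderate-to-good", 2))
  expect_identical(correlation_band(c(0.7500001, 1, -1)),
                   rep("very-good-to-excellent", 3))
  expect_error(correlation_band(1.2), "exceeds")
})

test_that("perfect and constructed correlations land in the right bands", {
  x <- seq_len(50)
  expect_identical(correlate(data.frame(x = x, y = x), "x", "y")$band,
                   "very-good-to-excellent")
  anti <- correlate(data.frame(x = x, y = -x), "x", "y")
  expect_equal(anti$r, -1)
  expect_identical(anti$band, "very-good-to-excellent")
  # bivariate normal with rho = 0.3 at n = 10000: comfortably "reasonable"
  set.seed(808)
  u <- rnorm(10000); v <- 0.3 * u + sqrt(1 - 0.09) * rnorm(10000)
  got <- correlate(data.frame(x = u, y = v), "x", "y")
  expect_identical(got$band, "reasonable")
  expect_equal(got$r, 0.3, tolerance = 0.05)
  expect_error(correlate(data.frame(x = x, y = rep(1, 50)), "x", "y"),
               "variance")
  expect_error(correlate(data.frame(x = x[1:3], y = x[1:3]), "x", "y"),
               "at least 4")
})

test_that("the test-selection gate is a pure function of Shapiro-Wilk p values", {
  set.seed(909)
  a <- rnorm(20); b <- rnorm(20)
  cmp <- compare_groups(two_group_table(a, b), "v")
  swa <- shapiro.test(a)$p.value; swb <- shapiro.test(b)$p.value
  expect_identical(cmp$test, if (min(swa, swb) > 0.05) "t" else "mann_whitney")
  expect_equal(unname(cmp$shapiro_p), c(swa, swb), tolerance = 1e-12)
  # grossly non-normal data fall through to Mann-Whitney
  skew <- exp(rnorm(30, sd = 2))
  cmp2 <- compare_groups(two_group_table(skew, exp(rnorm(30, sd = 2))), "v")
  expect_identical(cmp2$test, "mann_whitney")
})

test_that("widely separated groups are detected with the right direction", {
  set.seed(111)
  a <- rnorm(20)
  b <- rnorm(20) + 10
  cmp <- compare_groups(two_group_table(a, b), "v")
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$significant)
  expect_identical(cmp$direction, 1)
  expect_error(compare_groups(two_group_table(a[1:2], b), "v"), "at least 3")
  tab <- two_group_table(a, b); tab$v <- NA_real_
  expect_error(compare_groups(tab, "v"), "missing")
})

test_that("the report covers comparisons, correlations and recovery checks", {
  set.seed(222)
  n <- 24
  truth_Rp <- rlnorm(n, log(2), 0.4)
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control", "cf"), each = n / 2),
    R0 = rlnorm(n, log(3), 0.3), S = rnorm(n, -0.1, 0.03),
    R4 = rlnorm(n, log(3), 0.3), fr = runif(n, 8, 28),
    Xm = rnorm(n, -0.5, 0.5), Ax = rlnorm(n, log(5), 0.5),
    Cdyn = rlnorm(n, log(0.05), 0.4), Zrs4 = rlnorm(n, log(3), 0.3),
    R = rlnorm(n, log(1.8), 0.3),
    Rp = truth_Rp * exp(rnorm(n, 0, 0.05)),
    I = rlnorm(n, log(0.007), 0.2), C = rlnorm(n, log(0.01), 0.4),
    truth_Rp = truth_Rp)
  tab$Rt <- tab$R + tab$Rp
  rep1 <- cohort_report(tab)
  expect_length(rep1$comparisons, 13L)
  expect_length(rep1$correlations, 8L * 5L)
  expect_identical(rep1$recovery$Rp$band, "very-good-to-excellent")
  # single-group table: comparisons skipped with a notice, correlations kept
  solo <- cohort_report(tab[tab$group == "cf", ])
  expect_length(solo$comparisons, 0L)
  expect_match(paste(solo$notes, collapse = " "), "single group")
  expect_gt(length(solo$correlations), 0L)
})

test_that("duplicating rows strengthens p values but not the coefficient", {
  set.seed(333)
  tab <- data.frame(R0 = rnorm(20, 3), Rp = rnorm(20, 2))
  tab$Rp <- tab$Rp + 0.5 * tab$R0
  c1 <- correlate(tab, "R0", "Rp")
  c2 <- correlate(rbind(tab, tab), "R0", "Rp")
  expect_equal(c2$r, c1$r, tolerance = 1e-12)
  expect_lt(c2$p_value, c1$p_value)
})

test_that("report serialization is byte-stable", {
  set.seed(444)
  tab <- data.frame(
    group = rep(c("control", "cf"), each = 10),
    R0 = rnorm(20, 3), R = rnorm(20, 2), Rp = rnorm(20, 2))
  tab$Rt <- tab$R + tab$Rp
  rep1 <- cohort_report(tab)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report_json(rep1, f1)
  write_report_json(cohort_report(tab), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
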