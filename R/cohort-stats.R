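# Two-group statistics layer: normality-gated comparisons and Pearson
# correlations with the verbal classification bands used in pulmonary
# function research.

analysis_variables <- function() {
  c("R0", "S", "R4", "fr", "Xm", "Ax", "Cdyn", "Zrs4",
    "R", "Rp", "Rt", "I", "C")
}

#' Normality-gated two-group comparison
#'
#' Each group is screened with the Shapiro-Wilk W test; if both groups look
#' normal at the gate level, a two-sample Student's t test (pooled variance)
#' is used, otherwise the Mann-Whitney U test. Two-sided p values;
#' significance is claimed at p < `alpha`.
#'
#' @param table Data frame with a two-level `group` column and the variable.
#' @param variable Column name to compare.
#' @param alpha Significance level (default 0.05).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @return Object of class `comparison_result`: variable, test used
#'   (`"t"` or `"mann_whitney"`), statistic, p value, per-group mean, SD and
#'   n, direction (sign of second-group minus first-group mean), and the
#'   two Shapiro-Wilk p values.
#' @export
compare_groups <- function(table, variable, alpha = 0.05, gate_alpha = 0.05) {
  groups <- unique(as.character(table$group))
  if (length(groups) != 2L) stopf("table must contain exactly two groups")
  vals <- lapply(groups, function(g) {
    v <- table[[variable]][table$group == g]
    v[is.finite(v)]
  })
  if (all(lengths(vals) == 0)) stopf("variable '%s' is all-missing", variable)
  if (any(lengths(vals) < 3L)) {
    stopf("need at least 3 non-missing values per group for '%s'", variable)
  }
  sw <- vapply(vals, function(v) stats::shapiro.test(v)$p.value, numeric(1))
  normal <- all(sw > gate_alpha)
  ht <- if (normal) {
    stats::t.test(vals[[1]], vals[[2]], var.equal = TRUE)
  } else {
    stats::wilcox.test(vals[[1]], vals[[2]], exact = FALSE, correct = TRUE)
  }
  means <- vapply(vals, mean, numeric(1))
  structure(
    list(variable = variable,
         test = if (normal) "t" else "mann_whitney",
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         groups = groups,
         mean = means,
         sd = vapply(vals, stats::sd, numeric(1)),
         n = lengths(vals),
         direction = sign(means[2] - means[1]),
         shapiro_p = sw,
         significant = ht$p.value < alpha),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: %s vs %s, %s test, p = %.3g%s\n",
              x$variable, x$groups[1], x$groups[2],
              if (x$test == "t") "Student's t" else "Mann-Whitney U",
              x$p_value, if (x$significant) " *" else ""))
  cat(sprintf("  %s: %.4g +/- %.4g (n=%d); %s: %.4g +/- %.4g (n=%d)\n",
              x$groups[1], x$mean[1], x$sd[1], x$n[1],
              x$groups[2], x$mean[2], x$sd[2], x$n[2]))
  invisible(x)
}

#' Verbal classification band of a correlation coefficient
#'
#' Bands on the absolute coefficient, half-open and closed on the right:
#' \[0, 0.25\] small or none; (0.25, 0.50\] reasonable; (0.50, 0.75\]
#' moderate to good; (0.75, 1\] very good to excellent.
#'
#' @param r Pearson correlation coefficient in \[-1, 1\].
#' @return Character band label.
#' @export
correlation_band <- function(r) {
  vapply(abs(r), function(a) {
    if (is.na(a)) return(NA_character_)
    if (a > 1 + 1e-12) stopf("|r| exceeds 1")
    if (a <= 0.25) "small-or-none"
    else if (a <= 0.50) "reasonable"
    else if (a <= 0.75) "moderate-to-good"
    else "very-good-to-excellent"
  }, character(1))
}

#' Pearson correlation with classification band
#'
#' @param table Data frame holding both variables.
#' @param x,y Column names.
#' @return Object of class `correlation_result`: variable pair, r, two-sided
#'   p value, n and band label.
#' @export
correlate <- function(table, x, y) {
  xs <- table[[x]]; ys <- table[[y]]
  ok <- is.finite(xs) & is.finite(ys)
  if (sum(ok) < 4L) stopf("need at least 4 paired values for %s vs %s", x, y)
  if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) {
    stopf("zero variance in %s or %s", x, y)
  }
  ct <- stats::cor.test(xs[ok], ys[ok], method = "pearson")
  structure(
    list(x = x, y = y, r = unname(ct$estimate), p_value = ct$p.value,
         n = sum(ok), band = correlation_band(unname(ct$estimate))),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s vs %s: r = %.3f (p = %.3g, n = %d) [%s]\n",
              x$x, x$y, x$r, x$p_value, x$n, x$band))
  invisible(x)
}

#' Full statistical report for a cohort table
#'
#' Runs the two-group comparison for each of the 13 analysis variables
#' (eight FOT indices plus the fitted R, Rp, Rt, I, C) and the full
#' index-versus-fitted-parameter Pearson correlation matrix with bands.
#' When generator truth columns (`truth_R`, ...) are present, truth-versus-
#' fitted recovery correlations are added. With a single group the
#' comparisons are skipped with a notice and correlations still computed.
#'
#' @param table Cohort data frame (see [build_cohort_table]).
#' @param alpha Significance level for the comparisons.
#' @return Object of class `cohort_report`: lists `comparisons`,
#'   `correlations`, `recovery`, `notes`.
#' @export
cohort_report <- function(table, alpha = 0.05) {
  vars <- intersect(analysis_variables(), names(table))
  notes <- character(0)
  comparisons <- list()
  if (length(unique(table$group)) == 2L) {
    for (v in vars) {
      comparisons[[v]] <- tryCatch(
        compare_groups(table, v, alpha = alpha),
        error = function(e) {
          notes <<- c(notes, sprintf("comparison skipped for %s: %s",
                                     v, conditionMessage(e)))
          NULL
        })
    }
    comparisons <- Filter(Negate(is.null), comparisons)
  } else {
    notes <- c(notes, "single group: comparisons skipped")
  }
  index_vars <- intersect(c("R0", "S", "R4", "fr", "Xm", "Ax", "Cdyn", "Zrs4"),
                          names(table))
  param_vars <- intersect(c("R", "Rp", "Rt", "I", "C"), names(table))
  correlations <- list()
  for (ix in index_vars) {
    for (pv in param_vars) {
      correlations[[paste(ix, pv, sep = ".")]] <- tryCatch(
        correlate(table, ix, pv),
        error = function(e) {
          notes <<- c(notes, sprintf("correlation skipped for %s vs %s: %s",
                                     ix, pv, conditionMessage(e)))
          NULL
        })
    }
  }
  correlations <- Filter(Negate(is.null), correlations)
  recovery <- list()
  for (pv in param_vars) {
    tv <- paste0("truth_", pv)
    if (tv %in% names(table)) {
      recovery[[pv]] <- tryCatch(correlate(table, tv, pv),
                                 error = function(e) NULL)
    }
  }
  recovery <- Filter(Negate(is.null), recovery)
  structure(
    list(comparisons = comparisons, correlations = correlations,
         recovery = recovery, notes = notes, alpha = alpha),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d comparisons, %d correlations, %d recovery checks\n",
              length(x$comparisons), length(x$correlations), length(x$recovery)))
  for (cmp in x$comparisons) print(cmp)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Flatten a report into plain data frames (used by the writers and tests).
report_tables <- function(report) {
  comp <- do.call(rbind, lapply(report$comparisons, function(cm) {
    data.frame(variable = cm$variable, test = cm$test,
               statistic = cm$statistic, p_value = cm$p_value,
               group_a = cm$groups[1], mean_a = cm$mean[1], sd_a = cm$sd[1],
               n_a = cm$n[1],
               group_b = cm$groups[2], mean_b = cm$mean[2], sd_b = cm$sd[2],
               n_b = cm$n[2],
               direction = cm$direction, significant = cm$significant)
  }))
  corr <- do.call(rbind, lapply(report$correlations, function(cr) {
    data.frame(x = cr$x, y = cr$y, r = cr$r, p_value = cr$p_value,
               n = cr$n, band = cr$band)
  }))
  list(comparisons = comp, correlations = corr)
}
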