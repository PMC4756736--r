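#' Result of a group comparison, equivalence or non-inferiority test
#'
#' A light container mirroring how the bench reports each comparison:
#' the point estimate of the difference, its 95% confidence interval, the
#' margin (where applicable), the p-value and a verdict. Verdicts:
#' `"significant"` (difference detected), `"equivalent"` (both CI bounds
#' strictly inside the margin), `"non_inferior"` (CI lower bound above
#' `-margin`), `"fail"` (the test's criterion was not met).
#'
#' @param comparison label of the comparison.
#' @param estimate point difference, in the metric's units.
#' @param ci_low,ci_high 95% confidence bounds of the difference.
#' @param margin equivalence / non-inferiority margin (`NA` for plain
#'   difference tests).
#' @param p_value the test's p-value.
#' @param verdict one of `"significant"`, `"equivalent"`, `"non_inferior"`,
#'   `"fail"`.
#' @return object of class `stat_result`.
#' @export
stat_result <- function(comparison, estimate, ci_low, ci_high,
                        margin = NA_real_, p_value = NA_real_,
                        verdict = c("significant", "equivalent",
                                    "non_inferior", "fail")) {
  verdict <- match.arg(verdict)
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= estimate + 1e-12 && estimate <= ci_high + 1e-12))
    stop("confidence interval must contain the estimate")
  structure(list(comparison = comparison, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, margin = margin,
                 p_value = p_value, verdict = verdict),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  m <- if (is.na(x$margin)) "" else sprintf(", margin %g", x$margin)
  cat(sprintf("%s: diff %.4g [%.4g, %.4g]%s, p = %.4g -> %s\n",
              x$comparison, x$estimate, x$ci_low, x$ci_high, m,
              x$p_value, x$verdict))
  invisible(x)
}

#' Tabulate a list of stat_result objects
#'
#' @param results list of [stat_result] objects.
#' @return a data frame with one row per result.
#' @export
stat_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(comparison = r$comparison, estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, margin = r$margin,
               p_value = r$p_value, verdict = r$verdict,
               stringsAsFactors = FALSE)))
}

#' Tukey-Kramer honestly significant difference test
#'
#' All pairwise mean differences between groups, with studentized-range
#' adjusted p-values and simultaneous confidence intervals, using the
#' pooled variance from a one-way ANOVA (via [stats::aov()] and
#' [stats::TukeyHSD()]). With exactly two groups this reduces to a pooled
#' two-sample comparison.
#'
#' @param groups named list of numeric sample vectors (>= 2 groups, each
#'   with >= 2 values).
#' @param conf_level simultaneous confidence level.
#' @param alpha significance level for the verdict.
#' @return list of [stat_result] objects, one per pair, with verdict
#'   `"significant"` when the adjusted p-value is below `alpha` and
#'   `"fail"` otherwise.
#' @export
tukey_kramer <- function(groups, conf_level = 0.95, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 samples")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    grp = factor(rep(names(groups), ns), levels = names(groups))
  )
  fit <- stats::aov(value ~ grp, data = dat)
  if (stats::sigma(fit) <= 1e-10 * max(abs(dat$value), 1)) {
    mns <- tapply(dat$value, dat$grp, mean)
    if (max(mns) - min(mns) > 1e-10 * max(abs(dat$value), 1))
      stop("zero pooled variance with unequal group means")
  }
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$grp
  lapply(rownames(tk), function(nm) {
    row <- tk[nm, ]
    stat_result(comparison = nm, estimate = row[["diff"]],
                ci_low = row[["lwr"]], ci_high = row[["upr"]],
                p_value = row[["p adj"]],
                verdict = if (is.finite(row[["p adj"]]) &&
                              row[["p adj"]] < alpha) "significant" else "fail")
  })
}

# one-sided one-sample t p-value for H0: mean <= mu (alternative greater)
t_p_greater <- function(x, mu) {
  n <- length(x); s <- stats::sd(x)
  if (s == 0) return(if (mean(x) > mu) 0 else 1)
  stats::pt((mean(x) - mu) / (s / sqrt(n)), df = n - 1, lower.tail = FALSE)
}

#' Equivalence test (TOST) of paired differences against a margin
#'
#' Two one-sided t-tests of the mean paired difference against `-margin`
#' and `+margin`; the reported p-value is the larger of the two one-sided
#' p-values. The verdict is `"equivalent"` when the two-sided 95%
#' confidence interval of the mean difference lies strictly inside
#' `(-margin, margin)`.
#'
#' @param paired_diffs numeric vector of paired differences (>= 2 values).
#' @param margin equivalence margin (> 0), same units as the differences.
#' @param conf_level confidence level of the reported interval.
#' @param comparison label.
#' @return a [stat_result].
#' @export
equivalence_test <- function(paired_diffs, margin, conf_level = 0.95,
                             comparison = "equivalence") {
  if (margin <= 0) stop("margin must be > 0")
  n <- length(paired_diffs)
  if (n < 2L) stop("need at least 2 paired differences")
  m <- mean(paired_diffs); s <- stats::sd(paired_diffs)
  if (s == 0) {
    ci <- c(m, m)
    p <- if (abs(m) < margin) 0 else 1
  } else {
    se <- s / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- m + c(-1, 1) * tq * se
    p_low <- t_p_greater(paired_diffs, -margin)            # H0: mean <= -margin
    p_high <- stats::pt((m - margin) / se, df = n - 1)     # H0: mean >= +margin
    p <- max(p_low, p_high)
  }
  stat_result(comparison, m, ci[1], ci[2], margin = margin, p_value = p,
              verdict = if (ci[1] > -margin && ci[2] < margin)
                "equivalent" else "fail")
}

#' Non-inferiority test against a fixed margin
#'
#' One-sided test that the mean difference `treatment - reference` exceeds
#' `-margin` (for higher-is-better metrics; set `lower_better = TRUE` for
#' noise-SD-type metrics, which flips the difference sign before testing).
#' Paired comparisons use the per-replicate differences; unpaired ones use
#' Welch's unequal-variance t machinery. The verdict is `"non_inferior"`
#' when the two-sided 95% CI lower bound of the difference exceeds
#' `-margin`.
#'
#' @param treatment,reference numeric sample vectors.
#' @param margin non-inferiority margin (> 0).
#' @param paired whether samples are paired by replicate.
#' @param lower_better `TRUE` when smaller metric values are better.
#' @param conf_level confidence level of the reported interval.
#' @param comparison label.
#' @return a [stat_result].
#' @export
noninferiority_test <- function(treatment, reference, margin, paired = TRUE,
                                lower_better = FALSE, conf_level = 0.95,
                                comparison = "non-inferiority") {
  if (margin <= 0) stop("margin must be > 0")
  sgn <- if (lower_better) -1 else 1
  if (paired) {
    if (length(treatment) != length(reference))
      stop("paired samples must have equal length")
    d <- sgn * (treatment - reference)
    n <- length(d)
    if (n < 2L) stop("need at least 2 pairs")
    m <- mean(d); s <- stats::sd(d)
    if (s == 0) {
      ci <- c(m, m)
      p <- if (m > -margin) 0 else 1
    } else {
      se <- s / sqrt(n)
      tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
      ci <- m + c(-1, 1) * tq * se
      p <- t_p_greater(d, -margin)
    }
  } else {
    tt <- stats::t.test(sgn * treatment, sgn * reference,
                        conf.level = conf_level)
    m <- unname(diff(rev(tt$estimate)))
    ci <- as.numeric(tt$conf.int)
    p <- stats::t.test(sgn * treatment, sgn * reference, mu = -margin,
                       alternative = "greater")$p.value
  }
  stat_result(comparison, m, ci[1], ci[2], margin = margin, p_value = p,
              verdict = if (ci[1] > -margin) "non_inferior" else "fail")
}
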