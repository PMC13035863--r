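# Descriptive and inferential statistics: NRMSE, the constant-ratio /
# Bland-Altman analysis of contralateral tumor pairs, and the four-test
# battery for comparing fitted parameter distributions between groups.

#' Normalized root mean square error
#'
#' RMSE divided by the mean of the observed values. This mean-normalized
#' form is scale invariant: rescaling both series by a positive constant
#' leaves it unchanged.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return scalar NRMSE.
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || !length(observed))
    stop("`observed` and `predicted` must have equal positive length")
  m <- mean(observed)
  if (m == 0) stop("observations have zero mean; NRMSE undefined")
  sqrt(mean((observed - predicted)^2)) / m
}

#' Constant-ratio analysis of two-tumor measurements
#'
#' For each mouse, the ratio of the smaller to the larger tumor is divided by
#' that mouse's mean ratio; if the two tumors share one capacity and grow at
#' equal intrinsic rates, this normalized ratio stays at 1. Bland-Altman
#' agreement bands at `1 +/- 1.96 sd` (sd of all normalized ratios, pooled
#' over the cohort) give the verdict: a mouse is "constant-ratio" iff all of
#' its normalized ratios stay inside the bands.
#'
#' @param data a [measurement_series()] with sites `T1` and `T2`.
#' @return object of class `ratio_analysis`: list with `ratios` (per
#'   observation: mouse, day, ratio, normalized), `band_halfwidth`,
#'   `verdicts` (per mouse), `fraction_constant`, `mean_ratio` (mean of the
#'   per-mouse mean ratios) and `sd_ratio`.
#' @export
ratio_analysis <- function(data) {
  data <- measurement_series(data)
  mice <- .split_mice(data)
  rows <- list()
  for (mid in names(mice)) {
    m <- mice[[mid]]
    if (is.null(m$T1) || is.null(m$T2)) next
    days <- intersect(m$T1$day, m$T2$day)
    t1 <- m$T1$volume_mm3[match(days, m$T1$day)]
    t2 <- m$T2$volume_mm3[match(days, m$T2$day)]
    ok <- t1 > 0
    if (any(!ok))
      warning("mouse ", mid, ": excluding ", sum(!ok),
              " time points with zero T1 volume")
    if (!any(ok)) next
    rows[[mid]] <- data.frame(mouse_id = mid, day = days[ok],
                              ratio = t2[ok] / t1[ok],
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no mouse with both T1 and T2 measurements")
  ratios <- do.call(rbind, rows)
  mean_by_mouse <- tapply(ratios$ratio, ratios$mouse_id, mean)
  ratios$normalized <- as.numeric(ratios$ratio /
                                    mean_by_mouse[ratios$mouse_id])
  sdn <- sd(ratios$normalized)
  half <- 1.96 * sdn
  verdicts <- tapply(abs(ratios$normalized - 1) <= half, ratios$mouse_id, all)
  structure(list(ratios = ratios, band_halfwidth = half,
                 verdicts = verdicts,
                 fraction_constant = mean(verdicts),
                 mean_ratio = mean(mean_by_mouse),
                 sd_ratio = sd(ratios$ratio)),
            class = "ratio_analysis")
}

#' @export
print.ratio_analysis <- function(x, ...) {
  cat(sprintf(
    "<ratio_analysis> %d mice; %.0f%% constant-ratio; mean ratio %.3f (sd %.3f); band 1 +/- %.3f\n",
    length(x$verdicts), 100 * x$fraction_constant, x$mean_ratio, x$sd_ratio,
    x$band_halfwidth))
  invisible(x)
}

#' Anderson-Darling test for normality
#'
#' One-sample test of composite normality (mean and variance estimated),
#' using the standard small-sample correction
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and the published piecewise
#' exponential p-value approximation for the estimated-parameters case.
#'
#' @param x numeric sample, `n >= 8` recommended.
#' @return list with `statistic` (A*), `p.value`.
#' @export
ad_normality_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  s <- sd(x)
  if (s == 0) stop("constant sample: normality test undefined")
  z <- pnorm((x - mean(x)) / s)
  # guard the logs against underflow at extreme order statistics
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (Astar < 0.2) {
    1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  } else if (Astar < 0.34) {
    1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  } else if (Astar < 0.6) {
    exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  } else if (Astar < 10) {
    exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  } else 3.7e-24
  list(statistic = c(Astar = Astar), p.value = min(max(p, 0), 1))
}

#' Compare two fitted-parameter samples with the four-test battery
#'
#' Runs the Ansari-Bradley test (dispersion), the two-sample
#' Kolmogorov-Smirnov test (distribution), the Wilcoxon rank-sum test
#' (location) between the samples, and the Anderson-Darling normality test
#' on each sample separately. Tests that are undefined for a degenerate
#' sample report `NA` with the reason.
#'
#' @param values_a,values_b numeric samples, each of size >= 3.
#' @param alpha significance level for the verdict column.
#' @return object of class `test_report`: data.frame with `test`,
#'   `statistic`, `p_value`, `significant`, `note`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each sample needs at least 3 values")
  run <- function(name, expr) {
    out <- tryCatch({
      r <- suppressWarnings(expr())
      data.frame(test = name, statistic = unname(r$statistic),
                 p_value = r$p.value, significant = r$p.value < alpha,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(test = name, statistic = NA_real_, p_value = NA_real_,
                 significant = NA, note = conditionMessage(e),
                 stringsAsFactors = FALSE))
    out
  }
  rep <- rbind(
    run("ansari_bradley",
        function() ansari.test(values_a, values_b)),
    run("kolmogorov_smirnov",
        function() suppressWarnings(ks.test(values_a, values_b))),
    run("anderson_darling_a",
        function() ad_normality_test(values_a)),
    run("anderson_darling_b",
        function() ad_normality_test(values_b)),
    run("wilcoxon_rank_sum",
        function() wilcox.test(values_a, values_b,
                               exact = length(values_a) < 10 &&
                                 length(values_b) < 10)))
  class(rep) <- c("test_report", class(rep))
  rep
}
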