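# Model selection, parameter uncertainty and identifiability.

.bic_value <- function(objective, n, k) {
  if (objective <= 0) return(-Inf)  # a perfect fit: BIC degenerates
  n * log(objective / n) + k * log(n)
}

#' Bayesian Information Criterion of a fit
#'
#' Under i.i.d. Gaussian errors with profiled variance the BIC is
#' `n ln(SSE/n) + k ln(n)`, with `n` the number of residual contributions
#' and `k` the number of free parameters (each group-level parameter counted
#' once, each subject-level parameter once per mouse).
#'
#' @param fit a `sharedcap_fit`.
#' @return scalar BIC.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "sharedcap_fit"))
  .bic_value(fit$objective_value, fit$n_observations, fit$k_free_parameters)
}

#' Fit several two-tumor variants and rank them by BIC
#'
#' Fits each variant to the same data and returns the ranking (ascending
#' BIC, ties broken by the smaller parameter count).
#'
#' @param data a [measurement_series()] table.
#' @param variants list of [model_variant()] objects.
#' @param opt an [optimizer_config()].
#' @param ... passed to [fit_two_tumor()].
#' @return data.frame with one row per variant (`variant`, `objective`,
#'   `n`, `k`, `bic`, `rank`) and the fits in `attr(,"fits")`.
#' @export
model_select <- function(data, variants, opt = optimizer_config(), ...) {
  stopifnot(length(variants) >= 1)
  fits <- lapply(variants, function(v)
    fit_two_tumor(data, v, opt, compute_rse = FALSE, ...))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(variant = format(f$variant), objective = f$objective_value,
               n = f$n_observations, k = f$k_free_parameters, bic = f$bic,
               stringsAsFactors = FALSE)
  }))
  ord <- order(tab$bic, tab$k)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

.fd_jacobian <- function(fn, p, rel_h = 1e-6) {
  f0 <- fn(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- rel_h * max(abs(p[j]), 1e-4)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' Relative standard errors of fitted parameters
#'
#' Standard errors come from the Gauss-Newton approximation to the Fisher
#' information at the optimum: with residual Jacobian `J` (finite
#' differences) and `sigma^2 = SSE / (n - k)`, the covariance is
#' `sigma^2 (J'J)^-1`; the RSE is `100 * SE / |estimate|`. Parameters fitted
#' on a log10 scale are transformed back by the delta method. A singular
#' information matrix or a parameter at zero is reported as `NA` with the
#' `identifiable` flag set to `FALSE`.
#'
#' @param fit a `sharedcap_fit` from [fit_two_tumor()] (fits carrying a
#'   residual function).
#' @return data.frame with `parameter`, `estimate`, `se`, `rse_percent`,
#'   `identifiable`.
#' @export
relative_standard_error <- function(fit) {
  stopifnot(inherits(fit, "sharedcap_fit"))
  if (is.null(fit$internal$residuals_fn))
    stop("this fit does not carry a residual function; ",
         "relative standard errors are available for SSE-based fits")
  p <- fit$internal$par
  pm <- fit$internal$parmap
  r <- fit$internal$residuals_fn(p)
  n <- length(r); k <- length(p)
  if (n <= k) stop("need more observations than parameters for standard errors")
  J <- .fd_jacobian(fit$internal$residuals_fn, p)
  sigma2 <- sum(r^2) / (n - k)
  JtJ <- crossprod(J)
  cov_t <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  est_nat <- .from_trans(p, pm$trans)
  if (is.null(cov_t)) {
    se_nat <- rep(NA_real_, k)
  } else {
    se_t <- sqrt(pmax(diag(cov_t), 0))
    # delta method for the log10-scaled entries
    se_nat <- ifelse(pm$trans == "log10", se_t * est_nat * log(10), se_t)
  }
  rse <- ifelse(est_nat == 0, NA_real_, 100 * se_nat / abs(est_nat))
  data.frame(parameter = pm$name, estimate = est_nat, se = se_nat,
             rse_percent = rse,
             identifiable = is.finite(rse), stringsAsFactors = FALSE)
}

#' Profile likelihood of one fitted parameter
#'
#' Fixes the parameter at each grid value and re-optimizes all remaining
#' parameters, giving the profiled objective. Assuming Gaussian errors with
#' profiled variance, `-2 log L = n ln(SSE/n) + const`, so the 95% profile
#' bound lies where `n ln(SSE_prof / SSE_min)` crosses `qchisq(0.95, 1)`
#' (3.84). Bounds that never cross inside the grid are reported one-sided
#' (`-Inf`/`Inf`).
#'
#' @param fit a `sharedcap_fit`.
#' @param parameter parameter name as in `fit$parameters` /
#'   `fit$internal$parmap$name` (two-tumor) or one of the six model
#'   parameter names (metastatic).
#' @param grid grid of natural-scale values; default 21 points spanning one
#'   decade either side of the fitted value (log-spaced).
#' @param conf_level confidence level for the bounds.
#' @param config optimizer configuration for the re-fits (a smaller swarm
#'   than the main fit is usually enough).
#' @return object of class `profile_curve`: data.frame with `value`,
#'   `objective`, `delta_m2ll`; attributes `lower`, `upper`, `estimate`,
#'   `threshold`.
#' @export
profile_likelihood <- function(fit, parameter, grid = NULL, conf_level = 0.95,
                               config = optimizer_config(swarm_size = 15,
                                                         max_iterations = 40,
                                                         restarts = 1)) {
  stopifnot(inherits(fit, "sharedcap_fit"))
  est <- .profile_estimate(fit, parameter)
  if (is.null(grid)) {
    if (est <= 0) stop("default grid needs a positive estimate; supply `grid`")
    grid <- 10^seq(log10(est) - 1, log10(est) + 1, length.out = 21)
  }
  vals <- vapply(grid, function(v) {
    out <- tryCatch(fit$internal$refit_fn(setNames(v, parameter), config),
                    error = function(e) list(value = NA_real_))
    out$value
  }, numeric(1))
  n <- fit$n_observations
  best <- min(c(vals, fit$objective_value), na.rm = TRUE)
  delta <- n * log(vals / best)
  thr <- qchisq(conf_level, df = 1)
  curve <- data.frame(value = grid, objective = vals, delta_m2ll = delta)
  inside <- which(is.finite(delta) & delta <= thr)
  lower <- upper <- NA_real_
  if (length(inside)) {
    lo_i <- min(inside); hi_i <- max(inside)
    lower <- if (lo_i == 1) -Inf else
      .cross(grid[lo_i - 1], grid[lo_i], delta[lo_i - 1], delta[lo_i], thr)
    upper <- if (hi_i == length(grid)) Inf else
      .cross(grid[hi_i], grid[hi_i + 1], delta[hi_i], delta[hi_i + 1], thr)
  }
  structure(curve, class = c("profile_curve", class(curve)),
            parameter = parameter, estimate = est, lower = lower,
            upper = upper, threshold = thr, conf_level = conf_level)
}

.cross <- function(x0, x1, y0, y1, thr) {
  if (!is.finite(y0) || !is.finite(y1) || y1 == y0) return(x1)
  x0 + (thr - y0) * (x1 - x0) / (y1 - y0)
}

.profile_estimate <- function(fit, parameter) {
  if (fit$kind == "two_tumor") {
    pm <- fit$internal$parmap
    i <- match(parameter, pm$name)
    if (is.na(i)) stop("unknown parameter: ", parameter, "; available: ",
                       paste(pm$name, collapse = ", "))
    .from_trans(fit$internal$par[i], pm$trans[i])
  } else {
    if (parameter %in% names(fit$group_parameters))
      return(unname(fit$group_parameters[[parameter]]))
    i <- match(parameter, names(fit$parameters))
    if (is.na(i)) stop("unknown parameter: ", parameter)
    median(fit$parameters[[parameter]])
  }
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> %s: estimate %.4g, %g%% bounds [%.4g, %.4g]\n",
              attr(x, "parameter"), attr(x, "estimate"),
              100 * attr(x, "conf_level"), attr(x, "lower"),
              attr(x, "upper")))
  invisible(as.data.frame(x))
}
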