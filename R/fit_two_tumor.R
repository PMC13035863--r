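# Calibration of the two-tumor growth models: constant-ratio preprocessing,
# closed-form predictions wherever the variant admits them, PSO with an
# optional local polish, and assembly of the fit result.
#
# The initial volume of the larger tumor is fixed (default 1 mm^3, the
# inoculum convention); the smaller tumor starts at phi * T1_0 with phi the
# mean observed size ratio of that mouse. With equal rates and a shared
# capacity the coupled system collapses: the summed burden follows the
# single-tumor law and the ratio stays at phi, so predictions come from the
# closed forms; the same is true for all individual-capacity variants. Only
# shared capacity with unequal rates needs the ODE integrator.

.tt_predict_mouse <- function(law, capacity_mode, r1, r2, K1, K2, T10, phi,
                              days_T1, days_T2) {
  T20 <- phi * T10
  cf <- switch(law, gompertz = gompertz_closed_form,
               logistic = logistic_closed_form)
  if (law == "exponential") {
    return(list(T1 = exponential_closed_form(T10, r1, days_T1),
                T2 = if (T20 > 0) exponential_closed_form(T20, r2, days_T2)
                     else rep(0, length(days_T2))))
  }
  if (capacity_mode != "shared" || T20 == 0) {
    return(list(T1 = cf(T10, r1, K1, days_T1),
                T2 = if (T20 > 0) cf(T20, r2, K2, days_T2)
                     else rep(0, length(days_T2))))
  }
  if (isTRUE(all.equal(r1, r2))) {
    S0 <- T10 + T20
    list(T1 = cf(S0, r1, K1, days_T1) / (1 + phi),
         T2 = cf(S0, r1, K1, days_T2) * phi / (1 + phi))
  } else {
    grid <- sort(unique(c(0, days_T1, days_T2)))
    if (length(grid) < 2) grid <- c(grid, grid + 1)
    p <- two_tumor_params(r1 = r1, r2 = r2, capacity_mode = "shared", K = K1,
                          T1_0 = T10, T2_0 = T20)
    tr <- simulate_two_tumor(law, p, grid)
    list(T1 = approx(grid, tr$T1, days_T1)$y,
         T2 = approx(grid, tr$T2, days_T2)$y)
  }
}

# per-mouse preprocessing: measurement days per site and the mean size ratio
.tt_prepare <- function(data) {
  mice <- .split_mice(measurement_series(data))
  lapply(mice, function(m) {
    if (!is.null(m$T1) && !is.null(m$T2)) {
      shared_days <- intersect(m$T1$day, m$T2$day)
      t1 <- m$T1$volume_mm3[match(shared_days, m$T1$day)]
      t2 <- m$T2$volume_mm3[match(shared_days, m$T2$day)]
      ok <- t1 > 0
      if (any(!ok)) warning("excluding zero T1 volumes from ratio estimation")
      phi <- if (any(ok)) mean(t2[ok] / t1[ok]) else 0
      list(type = "DT", phi = min(max(phi, 0), 1),
           days_T1 = m$T1$day, obs_T1 = m$T1$volume_mm3,
           days_T2 = m$T2$day, obs_T2 = m$T2$volume_mm3)
    } else {
      s <- if (!is.null(m$PT)) m$PT else m$T1
      list(type = "ST", phi = 0, days_T1 = s$day, obs_T1 = s$volume_mm3,
           days_T2 = numeric(0), obs_T2 = numeric(0))
    }
  })
}

# parameter map: one row per free parameter with its transform and bounds
.tt_parmap <- function(variant, mouse_ids, K_lower, K_upper = 1e6,
                       r_bounds = c(0.005, 1)) {
  rows <- list()
  add <- function(name, mouse, what, trans, lower, upper)
    rows[[length(rows) + 1]] <<- data.frame(name = name, mouse = mouse,
                                            what = what, trans = trans,
                                            lower = lower, upper = upper,
                                            stringsAsFactors = FALSE)
  r_units <- if (variant$pooling$r == "population") "" else mouse_ids
  for (mid in r_units) {
    tag <- if (mid == "") "" else paste0("[", mid, "]")
    if (variant$rate_mode == "equal") {
      add(paste0("r", tag), mid, "r", "identity", r_bounds[1], r_bounds[2])
    } else {
      add(paste0("r1", tag), mid, "r1", "identity", r_bounds[1], r_bounds[2])
      add(paste0("r2", tag), mid, "r2", "identity", r_bounds[1], r_bounds[2])
    }
  }
  if (variant$law != "exponential") {
    K_units <- if (variant$pooling$K == "population") "" else mouse_ids
    uK <- log10(K_upper)
    for (mid in K_units) {
      tag <- if (mid == "") "" else paste0("[", mid, "]")
      # a population capacity must accommodate every mouse
      lK <- log10(if (mid == "") max(K_lower) else K_lower[[mid]])
      if (variant$capacity_mode == "individual_unequal") {
        add(paste0("K1", tag), mid, "K1", "log10", lK, uK)
        add(paste0("K2", tag), mid, "K2", "log10", lK, uK)
      } else {
        add(paste0("K", tag), mid, "K", "log10", lK, uK)
      }
    }
  }
  do.call(rbind, rows)
}

.from_trans <- function(v, trans) ifelse(trans == "log10", 10^v, v)
.to_trans <- function(v, trans) ifelse(trans == "log10", log10(v), v)

# decode an encoded (transformed) vector into per-mouse (r1, r2, K1, K2)
.tt_decode <- function(vec, pm, variant, mouse_ids) {
  nat <- .from_trans(vec, pm$trans)
  get1 <- function(what, mid) {
    i <- which(pm$what == what & pm$mouse == mid)
    if (!length(i)) i <- which(pm$what == what & pm$mouse == "")
    if (!length(i)) return(NA_real_)
    nat[i]
  }
  out <- lapply(mouse_ids, function(mid) {
    if (variant$rate_mode == "equal") {
      r1 <- r2 <- get1("r", mid)
    } else {
      r1 <- get1("r1", mid); r2 <- get1("r2", mid)
    }
    if (variant$law == "exponential") {
      K1 <- K2 <- NA_real_
    } else if (variant$capacity_mode == "individual_unequal") {
      K1 <- get1("K1", mid); K2 <- get1("K2", mid)
    } else {
      K1 <- K2 <- get1("K", mid)
    }
    list(r1 = r1, r2 = r2, K1 = K1, K2 = K2)
  })
  names(out) <- mouse_ids
  out
}

.tt_residuals <- function(vec, pm, variant, prep, T1_0) {
  pars <- .tt_decode(vec, pm, variant, names(prep))
  unlist(lapply(names(prep), function(mid) {
    pp <- pars[[mid]]; m <- prep[[mid]]
    pred <- .tt_predict_mouse(variant$law, variant$capacity_mode, pp$r1,
                              pp$r2, pp$K1, pp$K2, T1_0, m$phi,
                              m$days_T1, m$days_T2)
    c(m$obs_T1 - pred$T1, m$obs_T2 - pred$T2)
  }), use.names = FALSE)
}

#' Sum-of-squared-errors objective for the two-tumor experiment
#'
#' The calibration objective for longitudinal caliper data: the sum over all
#' mice, tumors and time points of squared differences between observed and
#' model-predicted volumes. Simulation failures propagate as `+Inf`.
#'
#' @param params data.frame with columns `mouse_id`, `r1`, `r2`, `K1`, `K2`
#'   (capacities ignored for the exponential law), one row per mouse in
#'   `data`.
#' @param data a [measurement_series()] table.
#' @param variant a [model_variant()].
#' @param T1_0 fixed initial volume of the larger tumor, mm^3.
#' @return scalar SSE (mm^6).
#' @export
sse_objective <- function(params, data, variant, T1_0 = 1) {
  stopifnot(inherits(variant, "model_variant"))
  prep <- .tt_prepare(data)
  tryCatch({
    res <- unlist(lapply(names(prep), function(mid) {
      i <- match(mid, params$mouse_id)
      if (is.na(i)) stop("no parameters for mouse ", mid)
      m <- prep[[mid]]
      pred <- .tt_predict_mouse(variant$law, variant$capacity_mode,
                                params$r1[i], params$r2[i], params$K1[i],
                                params$K2[i], T1_0, m$phi, m$days_T1,
                                m$days_T2)
      c(m$obs_T1 - pred$T1, m$obs_T2 - pred$T2)
    }))
    sum(res^2)
  }, error = function(e) Inf)
}

# run PSO + optional local polish on an encoded objective; the polish
# alternates Nelder-Mead and bounded quasi-Newton passes until converged,
# which matters on the long flat (r, K) valleys of barely-saturating data
.opt_box <- function(fn, lower, upper, config, polish = TRUE) {
  res <- pso_minimize(fn, lower, upper, config)
  if (!polish) return(res)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  for (round in 1:4) {
    improved <- FALSE
    nm <- if (length(res$par) < 2) NULL else
      tryCatch(optim(res$par, function(p) fn(clamp(p)),
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-14)),
               error = function(e) NULL)
    if (!is.null(nm) && is.finite(nm$value) && nm$value < res$value) {
      res$par <- clamp(nm$par); res$value <- nm$value; improved <- TRUE
    }
    bf <- tryCatch(optim(res$par, fn, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 300, factr = 10)),
                   error = function(e) NULL)
    if (!is.null(bf) && is.finite(bf$value) &&
        bf$value < res$value * (1 - 1e-12)) {
      res$par <- bf$par; res$value <- bf$value; improved <- TRUE
    }
    if (!improved) break
  }
  res
}

#' Fit the two-tumor model to caliper data
#'
#' Calibrates a [model_variant()] to a cohort by minimizing the
#' sum-of-squared-errors with particle swarm optimization (plus a local
#' polish). Preprocessing follows the constant-ratio analysis: each mouse's
#' initial size ratio `phi` is the mean of its observed `T2/T1` ratios, the
#' larger tumor starts at the fixed `T1_0`, and under `rate_mode = "equal"`
#' a single rate is fitted per unit. Fully subject-pooled variants are fitted
#' mouse by mouse (equivalent and faster); any population-pooled parameter
#' triggers a joint fit.
#'
#' @param data a [measurement_series()] table (sites `T1`/`T2`, or `PT` for
#'   single-tumor mice).
#' @param variant a [model_variant()].
#' @param opt an [optimizer_config()].
#' @param T1_0 fixed initial volume of the larger tumor, mm^3.
#' @param polish run a bounded quasi-Newton polish after PSO.
#' @param compute_rse attach relative standard errors.
#' @return object of class `sharedcap_fit`.
#' @examples
#' \donttest{
#' cfg <- two_tumor_config(n_mice = 3, seed = 42)
#' d <- generate_two_tumor_dataset(cfg)
#' fit <- fit_two_tumor(d$measurements, model_variant("gompertz", "shared"),
#'                      optimizer_config(swarm_size = 20, max_iterations = 60))
#' fit$parameters
#' }
#' @export
fit_two_tumor <- function(data, variant = model_variant(),
                          opt = optimizer_config(), T1_0 = 1, polish = TRUE,
                          compute_rse = TRUE) {
  stopifnot(inherits(variant, "model_variant"),
            inherits(opt, "optimizer_config"))
  data <- measurement_series(data)
  prep <- .tt_prepare(data)
  mouse_ids <- names(prep)
  n_obs <- sum(vapply(prep, function(m) length(m$obs_T1) + length(m$obs_T2),
                      numeric(1)))
  for (m in prep)
    if (length(m$obs_T1) < 3)
      stop("each mouse needs at least 3 time points per tumor")

  # K must at least accommodate each mouse's largest observed burden
  K_lower <- vapply(prep, function(m) {
    tot <- m$obs_T1
    if (length(m$obs_T2)) {
      shared <- intersect(m$days_T1, m$days_T2)
      tot <- c(tot, m$obs_T1[match(shared, m$days_T1)] +
                 m$obs_T2[match(shared, m$days_T2)])
    }
    max(tot)
  }, numeric(1)) * 1.001
  pm <- .tt_parmap(variant, mouse_ids, K_lower)
  if (nrow(pm) >= n_obs)
    stop("variant has more free parameters (", nrow(pm),
         ") than observations (", n_obs, ")")

  per_mouse <- variant$pooling$r == "subject" &&
    (variant$pooling$K == "subject" || variant$law == "exponential")

  if (per_mouse) {
    par_all <- numeric(nrow(pm)); value <- 0; conv <- TRUE
    for (i in seq_along(mouse_ids)) {
      mid <- mouse_ids[i]
      idx <- which(pm$mouse == mid)
      pmi <- pm[idx, , drop = FALSE]
      prep_i <- prep[mid]
      fn <- function(v) sum(.tt_residuals(v, pmi, variant, prep_i, T1_0)^2)
      cfg <- opt; cfg$seed <- opt$seed + i - 1L
      res <- .opt_box(fn, pmi$lower, pmi$upper, cfg, polish)
      par_all[idx] <- res$par; value <- value + res$value
      conv <- conv && res$converged
    }
  } else {
    fn <- function(v) sum(.tt_residuals(v, pm, variant, prep, T1_0)^2)
    res <- .opt_box(fn, pm$lower, pm$upper, opt, polish)
    par_all <- res$par; value <- res$value; conv <- res$converged
  }

  .tt_assemble_fit(par_all, value, pm, variant, prep, data, T1_0, opt, conv,
                   compute_rse)
}

.tt_assemble_fit <- function(par_all, value, pm, variant, prep, data, T1_0,
                             opt, converged, compute_rse) {
  mouse_ids <- names(prep)
  pars <- .tt_decode(par_all, pm, variant, mouse_ids)
  ptab <- do.call(rbind, lapply(mouse_ids, function(mid) {
    pp <- pars[[mid]]
    data.frame(mouse_id = mid, r1 = pp$r1, r2 = pp$r2, K1 = pp$K1,
               K2 = pp$K2, phi = prep[[mid]]$phi, T1_0 = T1_0,
               stringsAsFactors = FALSE)
  }))
  n_obs <- sum(vapply(prep, function(m) length(m$obs_T1) + length(m$obs_T2),
                      numeric(1)))
  k <- nrow(pm)
  fit <- structure(list(
    kind = "two_tumor", variant = variant, parameters = ptab,
    objective_value = value, n_observations = n_obs, k_free_parameters = k,
    bic = .bic_value(value, n_obs, k), seed = opt$seed, converged = converged,
    rse_percent = NULL,
    internal = list(
      par = par_all, parmap = pm, T1_0 = T1_0,
      residuals_fn = function(v) .tt_residuals(v, pm, variant, prep, T1_0),
      refit_fn = function(fixed, config, polish = TRUE) {
        .tt_refit(fixed, config, par_all, pm, variant, prep, T1_0, polish)
      })),
    class = "sharedcap_fit")
  if (compute_rse)
    fit$rse_percent <- tryCatch(relative_standard_error(fit),
                                error = function(e) NULL)
  fit
}

# re-optimize all parameters but one, used by profile_likelihood()
.tt_refit <- function(fixed, config, par_start, pm, variant, prep, T1_0,
                      polish = TRUE) {
  stopifnot(length(fixed) == 1, !is.null(names(fixed)))
  i <- match(names(fixed), pm$name)
  if (is.na(i)) stop("unknown parameter: ", names(fixed))
  vfix <- .to_trans(unname(fixed), pm$trans[i])
  free <- setdiff(seq_len(nrow(pm)), i)
  make_full <- function(v) { full <- numeric(nrow(pm)); full[i] <- vfix
                             full[free] <- v; full }
  fn <- function(v) sum(.tt_residuals(make_full(v), pm, variant, prep, T1_0)^2)
  if (!length(free)) return(list(value = fn(numeric(0)), par = numeric(0)))
  start <- par_start[free]
  res <- .opt_box(fn, pm$lower[free], pm$upper[free], config, polish)
  # the previous optimum is an excellent warm start; keep whichever is better
  pol <- tryCatch(optim(pmin(pmax(start, pm$lower[free]), pm$upper[free]), fn,
                        method = "L-BFGS-B", lower = pm$lower[free],
                        upper = pm$upper[free],
                        control = list(maxit = 200, factr = 1e4)),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < res$value)
    res <- list(par = pol$par, value = pol$value)
  res
}

#' @export
print.sharedcap_fit <- function(x, ...) {
  cat(sprintf("<sharedcap_fit: %s>\n", x$kind))
  if (x$kind == "two_tumor") cat("  variant:", format(x$variant), "\n")
  cat(sprintf("  objective %.6g on n = %d observations, k = %d, BIC = %.2f\n",
              x$objective_value, x$n_observations, x$k_free_parameters,
              x$bic))
  invisible(x)
}
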