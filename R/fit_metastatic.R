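# Calibration of the metastasis model: weighted relative-error objective and
# the nested group/subject particle-swarm fit.
#
# Each mouse contributes a longitudinal primary-tumor series and a single
# endpoint nodule table. The objective follows the two-scale design: primary
# volumes enter as relative errors (so early small and late large
# measurements weigh equally), and the endpoint nodules are compared in size
# against the simulated cumulative size distribution at their rank quantiles
# (largest observed nodule vs. the size at which the simulated cumulative
# count reaches 0.5, second largest vs. 1.5, ...). A mouse with no observed
# nodules is still informative: it contributes the simulated count of
# clinically relevant metastases as a penalty.

.met_transforms <- function() {
  # rates, capacities and fractions span decades: search them on log10 scale
  data.frame(
    name = .met_par_names,
    trans = c("log10", "log10", "log10", "log10", "identity", "log10"),
    lower = c(log10(1e-3), log10(1e-3), log10(500), log10(1e-4), 0,
              log10(1e-4)),
    upper = c(log10(0.3), log10(0.3), log10(1e5), log10(1), 1, log10(0.5)),
    stringsAsFactors = FALSE)
}

# direct simulation on an explicit grid (bypasses the dt regularization in
# simulate_metastatic so observation days are hit exactly)
.simulate_on_grid <- function(params, times, intervention = NULL,
                              rtol = 1e-8, atol = 1e-10, max_steps = 2e6) {
  u <- params$units
  K_cells <- volume_to_cells(params$K, u)
  x0 <- params$vartheta * volume_to_cells(params$X0, u)
  if (is.null(intervention)) intervention <- sharedcap::intervention()
  mu <- if (intervention$seeding_off) 0 else params$mu
  st <- intervention$surgery_time
  mode <- if (is.na(st)) 0L else match(intervention$surgery_mode,
                                       c("resect", "arrest"))
  m <- cpp_simulate_metastatic(params$a_PT, params$a_m, K_cells, mu,
                               params$chi, x0, times,
                               if (is.na(st)) NA_real_ else st, mode,
                               rtol, atol, max_steps)
  structure(list(times = times, x_PT = m[, "x_PT"], theta = m[, "theta"],
                 B = m[, "B"], G = m[, "G"], N = m[, "N"], M = m[, "M"],
                 params = params, intervention = intervention),
            class = "metastatic_trajectory")
}

# simulated sizes (cells) at the rank quantiles of the observed nodules;
# monotone cubic inversion keeps the sizes accurate on coarse output grids
.met_rank_sizes <- function(traj, q) {
  n <- length(traj$times)
  Nend <- traj$N[n]; Gend <- traj$G[n]
  Ninv <- .monotone_interp(cummax(traj$N), traj$times)
  Gfun <- .monotone_interp(traj$times, traj$G)
  s_q <- pmin(pmax(Ninv(q), traj$times[1]), traj$times[n])
  Gs <- Gfun(s_q)
  size <- exp(traj$params$a_m * (Gend - Gs))
  # q beyond the total seeded count -> born "after the end": size 1 cell
  size[q >= Nend] <- 1
  pmax(size, 1)
}

.met_mouse_objective <- function(par, mouse, X0, units, weights, dt = 0.5) {
  obj <- tryCatch({
    p <- metastatic_params(a_PT = par[["a_PT"]], a_m = par[["a_m"]],
                           K = par[["K"]], mu = par[["mu"]],
                           chi = par[["chi"]], vartheta = par[["vartheta"]],
                           X0 = X0, units = units)
    t_end <- mouse$endpoint
    times <- sort(unique(c(seq(0, t_end, by = dt), mouse$days, t_end)))
    # calibration runs at a looser tolerance and a hard step budget: absurd
    # parameter corners abort quickly and score +Inf instead of stalling
    tr <- .simulate_on_grid(p, times, rtol = 1e-6, atol = 1e-8,
                            max_steps = 50000)
    sim_pt <- cells_to_volume(tr$x_PT[match(mouse$days, times)], units)
    pt_term <- sum(abs(mouse$volumes - sim_pt) / mouse$volumes)
    m <- length(mouse$nodule_cells)
    if (m > 0) {
      q <- seq_len(m) - 0.5
      sim_sizes <- .met_rank_sizes(tr, q)
      obs <- sort(mouse$nodule_cells, decreasing = TRUE)
      met_term <- sum(abs(obs - sim_sizes) / obs)
    } else {
      # "no metastasis seen" argues against parameter sets that predict many
      met_term <- .count_above_raw(tr, t_end,
                                   units$relevance_threshold_cells)
    }
    weights[["PT"]] * pt_term + weights[["met"]] * met_term
  }, error = function(e) Inf)
  if (!is.finite(obj)) Inf else obj
}

#' Weighted relative-error objective for the metastasis experiment
#'
#' Combines the primary-tumor and metastasis scales: the sum over primary
#' measurements of `|obs - sim| / obs` plus, per observed nodule, the
#' relative size error against the simulated cumulative size distribution at
#' the nodule's rank quantile, weighted by `weights`. Mice without observed
#' nodules contribute the simulated clinically relevant count as a penalty.
#' Zero observed volumes are excluded with a warning.
#'
#' @param params a [metastatic_params()] (single mouse) or a named list of
#'   them, one per mouse in `data`.
#' @param data list with elements `series` (a [measurement_series()] with
#'   site `"PT"`), `nodules` (a [nodule_table()], possibly empty) and
#'   optionally `endpoints` (named vector of endpoint days per mouse;
#'   defaults to the last observation/nodule day).
#' @param weights named numeric, `c(PT = 1, met = 1)`.
#' @return scalar objective.
#' @export
weighted_relative_objective <- function(params, data,
                                        weights = c(PT = 1, met = 1)) {
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not both zero")
  mice <- .met_prepare(data)
  if (inherits(params, "metastatic_params"))
    params <- setNames(rep(list(params), length(mice)), names(mice))
  sum(vapply(names(mice), function(mid) {
    p <- params[[mid]]
    if (is.null(p)) stop("no parameters for mouse ", mid)
    par <- c(a_PT = p$a_PT, a_m = p$a_m, K = p$K, mu = p$mu, chi = p$chi,
             vartheta = p$vartheta)
    .met_mouse_objective(par, mice[[mid]], p$X0, p$units, weights)
  }, numeric(1)))
}

# Cheap initialization for the nested fit. The primary-tumor series alone
# pins (a_PT, vartheta, K) through the Gompertz closed form on log volumes;
# the largest nodule gives a first guess at a_m through the characteristic
# size; the observed nodule count scaled by the seeding integral gives mu.
# Returns natural-scale values; failures fall back to mid-box.
.met_heuristic_init <- function(mice, X0, units) {
  cells <- units$cells_per_mm3
  per <- lapply(mice, function(m) {
    obs <- log(pmax(m$volumes, 1e-8))
    fn <- function(p) {
      a <- 10^p[1]; x0 <- 10^p[2] * X0 * cells; K <- 10^p[3] * cells
      if (K <= x0) return(1e10)
      pred <- log(K) + log(x0 / K) * exp(-a * m$days) - log(cells)
      sum((obs - pred)^2)
    }
    best <- NULL
    for (s in list(c(-1.5, -2, 3.8), c(-1, -1.5, 3.5), c(-2, -2.5, 4.2))) {
      r <- tryCatch(optim(s, fn, control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
    }
    if (is.null(best)) return(NULL)
    a <- 10^best$par[1]; vth <- 10^best$par[2]; K_mm3 <- 10^best$par[3]
    x0 <- vth * X0 * cells
    t_end <- m$endpoint
    G_end <- log(K_mm3 * cells / x0) / a * (1 - exp(-a * t_end))
    a_m0 <- if (length(m$nodule_cells))
      log(max(m$nodule_cells)) / max(G_end, 1e-6) else a
    # seeding integral at chi = 0.3 over the fitted primary trajectory
    tt <- seq(0, t_end, length.out = 100)
    xt <- K_mm3 * cells * exp(log(x0 / (K_mm3 * cells)) * exp(-a * tt))
    seed_int <- sum(xt^0.3 * (1 - xt / (K_mm3 * cells))) * (t_end / 100)
    mu0 <- max(length(m$nodule_cells), 1) / max(seed_int, 1e-6)
    list(a = a, vth = vth, K = K_mm3, a_m = a_m0, mu = mu0)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) return(NULL)
  g <- function(f) vapply(per, f, numeric(1))
  list(a_PT = median(g(function(x) x$a)),
       vartheta = median(g(function(x) x$vth)),
       mu = median(g(function(x) x$mu)),
       chi = 0.3,
       a_m = g(function(x) x$a_m),
       K = g(function(x) x$K),
       ids = names(per))
}

# normalize the (series, nodules, endpoints) bundle into per-mouse pieces
.met_prepare <- function(data) {
  series <- measurement_series(data$series)
  series <- series[series$site == "PT", , drop = FALSE]
  if (!nrow(series)) stop("no primary-tumor (site PT) measurements")
  nod <- if (!is.null(data$nodules) && nrow(as.data.frame(data$nodules)) > 0)
    nodule_table(data$nodules) else NULL
  ids <- unique(series$mouse_id)
  out <- lapply(ids, function(mid) {
    s <- series[series$mouse_id == mid, ]
    zero <- s$volume_mm3 <= 0
    if (any(zero)) {
      warning("excluding ", sum(zero), " zero-volume observations for mouse ",
              mid)
      s <- s[!zero, ]
    }
    nd <- if (!is.null(nod)) nod[nod$mouse_id == mid, ] else NULL
    endpoint <- if (!is.null(data$endpoints) && mid %in% names(data$endpoints))
      data$endpoints[[mid]]
    else max(c(s$day, nd$endpoint_day))
    list(days = s$day, volumes = s$volume_mm3,
         nodule_cells = if (!is.null(nd) && nrow(nd))
           nd$volume_mm3 * 1e6 else numeric(0),
         endpoint = endpoint)
  })
  names(out) <- ids
  out
}

#' Fit the metastasis model with nested parameter sharing
#'
#' Group-level parameters (shared by the cohort) are optimized by particle
#' swarm in an outer loop; inside each outer evaluation, every mouse's
#' subject-level parameters are re-optimized (Nelder-Mead, warm-started from
#' that mouse's previous optimum). The default [sharing_mask()] is the
#' parsimonious configuration: group `a_PT, mu, vartheta`, subject
#' `a_m, chi, K`. With every parameter subject-level the outer loop
#' disappears and the fit is a direct per-mouse joint optimization.
#'
#' @param data as in [weighted_relative_objective()].
#' @param mask a [sharing_mask()].
#' @param opt an [optimizer_config()] for the outer swarm.
#' @param X0 inoculated volume, mm^3 (known from the experiment design).
#' @param units a [unit_convention()].
#' @param weights objective weights, see [weighted_relative_objective()].
#' @param inner_maxit Nelder-Mead iterations per inner solve.
#' @param dt simulation output step, days.
#' @param bounds optional named list overriding per-parameter search bounds
#'   (each a `c(lower, upper)` on the natural scale).
#' @return object of class `sharedcap_fit` with per-mouse and group
#'   parameter tables.
#' @export
fit_metastatic <- function(data, mask = sharing_mask(),
                           opt = optimizer_config(), X0, units = unit_convention(),
                           weights = c(PT = 1, met = 1), inner_maxit = 200,
                           dt = 0.5, bounds = NULL) {
  stopifnot(inherits(mask, "sharing_mask"), inherits(opt, "optimizer_config"))
  mice <- .met_prepare(data)
  if (!length(mice)) stop("empty dataset")
  ids <- names(mice)

  tf <- .met_transforms()
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      i <- match(nm, tf$name)
      if (is.na(i)) stop("unknown parameter in bounds: ", nm)
      tf$lower[i] <- .to_trans(bounds[[nm]][1], tf$trans[i])
      tf$upper[i] <- .to_trans(bounds[[nm]][2], tf$trans[i])
    }
  }
  gi <- match(mask$group, tf$name)    # outer (group) rows of tf
  si <- match(mask$subject, tf$name)  # inner (subject) rows

  # fixed per-mouse starting points from the closed-form heuristic
  # (PT-series Gompertz fit + nodule extremes), plus a warm-start cache used
  # only in the final refinement
  warm <- new.env(parent = emptyenv())
  heur_start <- new.env(parent = emptyenv())
  mid_box <- (tf$lower + tf$upper) / 2
  heur <- tryCatch(.met_heuristic_init(mice, X0, units),
                   error = function(e) NULL)
  heur_full <- NULL
  if (!is.null(heur)) {
    heur_full <- setNames(mid_box, tf$name)
    for (nm in c("a_PT", "mu", "vartheta", "chi")) {
      i <- match(nm, tf$name)
      heur_full[i] <- min(max(.to_trans(heur[[nm]], tf$trans[i]),
                              tf$lower[i]), tf$upper[i])
    }
    for (mid in heur$ids) {
      sv <- setNames(mid_box, tf$name)
      j <- match(mid, heur$ids)
      sv[match("a_m", tf$name)] <- .to_trans(unname(heur$a_m[j]), "log10")
      sv[match("K", tf$name)] <- .to_trans(unname(heur$K[j]), "log10")
      sv[match("chi", tf$name)] <- 0.3
      heur_start[[mid]] <- pmin(pmax(sv[si], tf$lower[si]), tf$upper[si])
    }
  }

  decode <- function(g_vec, s_vec) {
    par <- numeric(nrow(tf)); names(par) <- tf$name
    par[gi] <- .from_trans(g_vec, tf$trans[gi])
    par[si] <- .from_trans(s_vec, tf$trans[si])
    par
  }

  # During the outer swarm the inner solve must be a *deterministic*
  # function of (mouse, group parameters): a single Nelder-Mead from the
  # heuristic start. History-dependent warm starts are only added in the
  # final refinement, where the group parameters barely move.
  inner_solve <- function(mid, g_vec, maxit, use_warm = FALSE) {
    m <- mice[[mid]]
    fn <- function(s_vec) {
      s_vec <- pmin(pmax(s_vec, tf$lower[si]), tf$upper[si])
      .met_mouse_objective(decode(g_vec, s_vec), m, X0, units, weights, dt)
    }
    if (!length(si)) return(list(par = numeric(0), value = fn(numeric(0))))
    starts <- list(if (!is.null(heur_start[[mid]])) heur_start[[mid]]
                   else mid_box[si])
    if (use_warm && !is.null(warm[[mid]]))
      starts <- c(starts, list(warm[[mid]]))
    best <- NULL
    for (s0 in starts) {
      # one simplex restart at the interim optimum sharpens convergence a lot
      r <- tryCatch({
        r1 <- optim(s0, fn, method = "Nelder-Mead",
                    control = list(maxit = maxit))
        optim(r1$par, fn, method = "Nelder-Mead",
              control = list(maxit = maxit))
      }, error = function(e) list(par = s0, value = Inf))
      if (is.null(best) || r$value < best$value) best <- r
    }
    best$par <- pmin(pmax(best$par, tf$lower[si]), tf$upper[si])
    if (use_warm) warm[[mid]] <- best$par
    best
  }

  outer_fn <- function(g_vec) {
    sum(vapply(ids, function(mid) inner_solve(mid, g_vec, inner_maxit)$value,
               numeric(1)))
  }

  if (length(gi)) {
    # the count-based mu guess misses the undetected micro-metastases, so
    # seed additional particles with mu scaled up by half and full decades
    init <- NULL
    if (!is.null(heur_full)) {
      rows <- list(heur_full[gi])
      i_mu <- match(match("mu", tf$name), gi)
      if (!is.na(i_mu)) {
        for (up in c(0.7, 1.4, 2.1)) {
          v <- heur_full[gi]; v[i_mu] <- v[i_mu] + up
          rows[[length(rows) + 1]] <- v
        }
      }
      init <- do.call(rbind, lapply(rows, function(v)
        pmin(pmax(v, tf$lower[gi]), tf$upper[gi])))
    }
    res <- pso_minimize(outer_fn, tf$lower[gi], tf$upper[gi], opt,
                        init = init)
    g_best <- res$par
    best_val <- res$value
    conv <- res$converged
    # alternate a local group polish with fully converged inner solves; two
    # rounds are enough to settle the group/subject coupling
    for (round in 1:2) {
      pol <- tryCatch(optim(g_best, function(v) {
        v <- pmin(pmax(v, tf$lower[gi]), tf$upper[gi])
        sum(vapply(ids, function(mid)
          inner_solve(mid, v, inner_maxit)$value, numeric(1)))
      }, method = "Nelder-Mead",
      control = list(maxit = 80, reltol = 1e-9)),
      error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < best_val) {
        g_best <- pmin(pmax(pol$par, tf$lower[gi]), tf$upper[gi])
        best_val <- pol$value
      } else break
      for (mid in ids) inner_solve(mid, g_best, 2 * inner_maxit,
                                   use_warm = TRUE)
    }
  } else {
    g_best <- numeric(0)
    conv <- TRUE
  }
  # final, longer inner solves at the optimal group parameters
  inner_best <- lapply(ids, function(mid)
    inner_solve(mid, g_best, 4 * inner_maxit, use_warm = TRUE))
  names(inner_best) <- ids
  value <- sum(vapply(inner_best, `[[`, numeric(1), "value"))

  group_nat <- setNames(.from_trans(g_best, tf$trans[gi]), tf$name[gi])
  ptab <- do.call(rbind, lapply(ids, function(mid) {
    par <- decode(g_best, inner_best[[mid]]$par)
    cbind(data.frame(mouse_id = mid, stringsAsFactors = FALSE),
          as.data.frame(as.list(par)))
  }))
  n_obs <- sum(vapply(mice, function(m)
    length(m$days) + max(length(m$nodule_cells), 1L), numeric(1)))
  k <- length(gi) + length(si) * length(ids)

  structure(list(
    kind = "metastatic", mask = mask, parameters = ptab,
    group_parameters = group_nat, objective_value = value,
    n_observations = n_obs, k_free_parameters = k,
    bic = .bic_value(value, n_obs, k), seed = opt$seed, converged = conv,
    rse_percent = NULL,
    internal = list(
      tf = tf, gi = gi, si = si, X0 = X0, units = units, weights = weights,
      g_par = g_best,
      s_par = lapply(inner_best, `[[`, "par"),
      mice = mice, dt = dt,
      refit_fn = function(fixed, config, polish = TRUE) {
        .met_refit(fixed, config, mice, tf, gi, si, g_best,
                   lapply(inner_best, `[[`, "par"), X0, units, weights,
                   inner_maxit, dt)
      })),
    class = "sharedcap_fit")
}

# profile refit: fix one *group* parameter and re-optimize the rest
.met_refit <- function(fixed, config, mice, tf, gi, si, g_start, s_start,
                       X0, units, weights, inner_maxit, dt) {
  stopifnot(length(fixed) == 1, !is.null(names(fixed)))
  nm <- names(fixed)
  i_tf <- match(nm, tf$name)
  if (is.na(i_tf)) stop("unknown parameter: ", nm)
  vfix <- .to_trans(unname(fixed), tf$trans[i_tf])
  ids <- names(mice)
  warm <- new.env(parent = emptyenv())
  for (mid in ids) warm[[mid]] <- s_start[[mid]]

  if (i_tf %in% gi) {
    g_pos <- match(i_tf, gi)
    free <- setdiff(seq_along(gi), g_pos)
    make_g <- function(v) { g <- numeric(length(gi)); g[g_pos] <- vfix
                            g[free] <- v; g }
    obj_mouse <- function(mid, g_vec) {
      m <- mice[[mid]]
      fn <- function(s_vec) {
        s_vec <- pmin(pmax(s_vec, tf$lower[si]), tf$upper[si])
        par <- numeric(nrow(tf)); names(par) <- tf$name
        par[gi] <- .from_trans(g_vec, tf$trans[gi])
        par[si] <- .from_trans(s_vec, tf$trans[si])
        .met_mouse_objective(par, m, X0, units, weights, dt)
      }
      if (!length(si)) return(fn(numeric(0)))
      r <- optim(warm[[mid]], fn, method = "Nelder-Mead",
                 control = list(maxit = inner_maxit))
      warm[[mid]] <- pmin(pmax(r$par, tf$lower[si]), tf$upper[si])
      r$value
    }
    fn_outer <- function(v)
      sum(vapply(ids, obj_mouse, numeric(1), g_vec = make_g(v)))
    if (!length(free)) return(list(value = fn_outer(numeric(0))))
    start <- g_start[free]
    r <- optim(start, fn_outer, method = "Nelder-Mead",
               control = list(maxit = 60))
    list(value = r$value, par = r$par)
  } else {
    # subject-level parameter: fixed for every mouse, others re-optimized
    s_pos <- match(i_tf, si)
    free_s <- setdiff(seq_along(si), s_pos)
    total <- 0
    for (mid in ids) {
      m <- mice[[mid]]
      fn <- function(v) {
        s_vec <- numeric(length(si)); s_vec[s_pos] <- vfix; s_vec[free_s] <- v
        s_vec <- pmin(pmax(s_vec, tf$lower[si]), tf$upper[si])
        par <- numeric(nrow(tf)); names(par) <- tf$name
        par[gi] <- .from_trans(g_start, tf$trans[gi])
        par[si] <- .from_trans(s_vec, tf$trans[si])
        .met_mouse_objective(par, m, X0, units, weights, dt)
      }
      if (!length(free_s)) { total <- total + fn(numeric(0)); next }
      r <- optim(s_start[[mid]][free_s], fn, method = "Nelder-Mead",
                 control = list(maxit = 2 * inner_maxit))
      total <- total + r$value
    }
    list(value = total)
  }
}
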