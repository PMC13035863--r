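# Synthetic experiments with the statistical structure the analysis assumes:
# Gompertz-shaped caliper series with multiplicative log-normal measurement
# noise, sacrifice at a caliper ceiling, and endpoint nodule tables drawn
# from the metastasis model's seeding intensity by an inhomogeneous Poisson
# mechanism. All randomness flows from the config's single seed.

#' Configuration for a synthetic two-tumor experiment
#'
#' Defaults emulate the contralateral LLC experiment: cohorts of 10 mice,
#' per-mouse growth rates around 0.085/day (sd 0.024) and capacities around
#' 7.74e3 mm^3, initial size ratios around 0.99 (sd 0.23, folded into (0,1]),
#' the larger tumor starting at 1 mm^3, daily caliper measurements and
#' sacrifice at 1.5e3 mm^3 per tumor. Noise is multiplicative log-normal
#' with coefficient of variation `sigma`.
#'
#' @param n_mice number of mice.
#' @param law growth law name.
#' @param r_median,r_sd location/spread of the log-normal growth-rate
#'   distribution across mice.
#' @param K_median,K_sd as above for the carrying capacity (mm^3).
#' @param phi_mean,phi_sd initial ratio distribution (normal, folded into
#'   (0, 1]); set `phi_mean = 0` with `phi_sd = 0` for a single-tumor cohort.
#' @param T1_0 initial volume of the larger tumor, mm^3.
#' @param schedule measurement days.
#' @param sigma noise CV; 0 disables noise.
#' @param ceiling_mm3 sacrifice threshold per tumor, mm^3.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
two_tumor_config <- function(n_mice = 10, law = "gompertz", r_median = 0.085,
                             r_sd = 0.024, K_median = 7740, K_sd = 1.33e4,
                             phi_mean = 0.991, phi_sd = 0.231, T1_0 = 1,
                             schedule = 1:40, sigma = 0.05,
                             ceiling_mm3 = 1500, seed = 1L) {
  stopifnot(sigma >= 0, n_mice >= 1, all(diff(schedule) > 0))
  structure(list(kind = "two_tumor", n_mice = n_mice, law = law,
                 r_median = r_median, r_sd = r_sd, K_median = K_median,
                 K_sd = K_sd, phi_mean = phi_mean, phi_sd = phi_sd,
                 T1_0 = T1_0, schedule = schedule, sigma = sigma,
                 ceiling_mm3 = ceiling_mm3, seed = as.integer(seed)),
            class = "synthetic_config")
}

# log-normal with given median and approximate sd on the natural scale
.rlnorm_med <- function(n, med, sd) {
  if (sd <= 0) return(rep(med, n))
  cv <- sd / med
  sigma <- sqrt(log(1 + min(cv, 10)^2))
  med * exp(rnorm(n, 0, sigma))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv()) else old <- NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic two-tumor (or single-tumor) dataset
#'
#' Simulates each mouse with the shared-capacity model, applies
#' multiplicative log-normal noise, and truncates each mouse's schedule at
#' the first measurement exceeding the caliper ceiling (the sacrifice rule;
#' the crossing measurement is kept). Deterministic per seed.
#'
#' @param config a [two_tumor_config()].
#' @return list with `measurements` (a [measurement_series()];
#'   sites `T1`/`T2`, or `PT` for single-tumor cohorts) and `truth`
#'   (data.frame of generating parameters per mouse).
#' @export
generate_two_tumor_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"), config$kind == "two_tumor")
  .with_seed(config$seed, {
    n <- config$n_mice
    r <- .rlnorm_med(n, config$r_median, config$r_sd)
    K <- .rlnorm_med(n, config$K_median, config$K_sd)
    phi <- if (config$phi_mean <= 0) rep(0, n) else {
      ph <- rnorm(n, config$phi_mean, config$phi_sd)
      ph <- abs(ph)
      ifelse(ph > 1, 1 / ph, pmax(ph, 0.05))
    }
    single <- all(phi == 0)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- two_tumor_params(r1 = r[i], capacity_mode = "shared", K = K[i],
                            T1_0 = config$T1_0, phi = phi[i])
      tr <- simulate_two_tumor(config$law, p, c(0, config$schedule))
      keep <- -1L  # drop the t=0 anchor row
      T1 <- tr$T1[keep]; T2 <- tr$T2[keep]
      if (config$sigma > 0) {
        T1 <- T1 * exp(rnorm(length(T1), 0, config$sigma))
        T2 <- T2 * exp(rnorm(length(T2), 0, config$sigma))
      }
      over <- which(pmax(T1, T2) > config$ceiling_mm3)
      last <- if (length(over)) over[1] else length(T1)
      days <- config$schedule[seq_len(last)]
      mid <- sprintf("m%02d", i)
      rows[[i]] <- if (single) {
        data.frame(mouse_id = mid, day = days, site = "PT",
                   volume_mm3 = T1[seq_len(last)], stringsAsFactors = FALSE)
      } else {
        rbind(data.frame(mouse_id = mid, day = days, site = "T1",
                         volume_mm3 = T1[seq_len(last)],
                         stringsAsFactors = FALSE),
              data.frame(mouse_id = mid, day = days, site = "T2",
                         volume_mm3 = T2[seq_len(last)],
                         stringsAsFactors = FALSE))
      }
    }
    truth <- data.frame(mouse_id = sprintf("m%02d", seq_len(n)), r = r,
                        K = K, phi = phi, T1_0 = config$T1_0,
                        stringsAsFactors = FALSE)
    list(measurements = measurement_series(do.call(rbind, rows)),
         truth = truth)
  })
}

#' Configuration for a synthetic metastasis experiment
#'
#' Defaults emulate the moderately metastatic mammary-tumor cohort: group
#' parameters `a_PT = 0.032`, `mu = 0.016`, `vartheta = 0.011`, inoculation
#' `X0 = 3` mm^3, subject parameters sampled around `a_m = 0.026`,
#' `chi = 0.279`, `K = 6.8e3` mm^3, twice-weekly calipers to day 60 with
#' sacrifice at 2.0e3 mm^3, and endpoint H&E nodule tables listing all
#' metastases above the detection limit (the clinical relevance threshold by
#' default).
#'
#' @param n_mice number of mice.
#' @param a_PT,mu,vartheta,X0 group-level parameters.
#' @param a_m_median,a_m_sd,chi_median,chi_sd,K_median,K_sd subject-level
#'   parameter distributions (log-normal for `a_m` and `K`; normal clamped
#'   to [0.05, 0.95] for `chi`).
#' @param schedule measurement days (twice weekly by default).
#' @param t_end endpoint day.
#' @param sigma caliper noise CV.
#' @param ceiling_mm3 sacrifice threshold for the primary, mm^3.
#' @param detection_limit_cells smallest nodule reported in the endpoint
#'   table, cells.
#' @param nodule_sampling `"poisson"` draws an integer nodule table from the
#'   seeding intensity (the realistic default); `"deterministic"` lists the
#'   model's expected nodules at their rank quantiles, the zero-noise analog
#'   used for closed-loop recovery tests.
#' @param units a [unit_convention()].
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
metastatic_config <- function(n_mice = 3, a_PT = 0.032, mu = 0.016,
                              vartheta = 0.011, X0 = 3, a_m_median = 0.026,
                              a_m_sd = 0.008, chi_median = 0.279,
                              chi_sd = 0.05, K_median = 6.8e3, K_sd = 1.7e3,
                              schedule = seq(7, 120, by = 3.5), t_end = 60,
                              sigma = 0.05, ceiling_mm3 = 2000,
                              detection_limit_cells = 3500,
                              nodule_sampling = c("poisson", "deterministic"),
                              units = unit_convention(), seed = 1L) {
  stopifnot(sigma >= 0, n_mice >= 1)
  nodule_sampling <- match.arg(nodule_sampling)
  structure(list(kind = "metastatic", n_mice = n_mice, a_PT = a_PT, mu = mu,
                 vartheta = vartheta, X0 = X0, a_m_median = a_m_median,
                 a_m_sd = a_m_sd, chi_median = chi_median, chi_sd = chi_sd,
                 K_median = K_median, K_sd = K_sd, schedule = schedule,
                 t_end = t_end, sigma = sigma, ceiling_mm3 = ceiling_mm3,
                 detection_limit_cells = detection_limit_cells,
                 nodule_sampling = nodule_sampling,
                 units = units, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic metastasis dataset
#'
#' Each mouse gets a primary-tumor caliper series (log-normal noise,
#' sacrifice rule as in [generate_two_tumor_dataset()]) and an endpoint
#' nodule table. Nodules are drawn by an inhomogeneous Poisson mechanism
#' with the model's seeding intensity `B(s)`: the number of metastases is
#' Poisson with mean `N(t_end)`, their birth times invert the cumulative
#' intensity, their sizes follow the characteristics, and only nodules above
#' the detection limit are listed (H&E cannot see a handful of cells).
#' Deterministic per seed.
#'
#' @param config a [metastatic_config()].
#' @return list with `series` (PT [measurement_series()]), `nodules`
#'   (a [nodule_table()]), `endpoints` (named vector of per-mouse endpoint
#'   days) and `truth` (generating parameters per mouse).
#' @export
generate_metastatic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"), config$kind == "metastatic")
  .with_seed(config$seed, {
    n <- config$n_mice
    a_m <- .rlnorm_med(n, config$a_m_median, config$a_m_sd)
    chi <- pmin(pmax(rnorm(n, config$chi_median, config$chi_sd), 0.05), 0.95)
    K <- .rlnorm_med(n, config$K_median, config$K_sd)
    u <- config$units
    srows <- list(); nrows <- list(); endpoints <- numeric(n)
    for (i in seq_len(n)) {
      mid <- sprintf("m%02d", i)
      p <- metastatic_params(a_PT = config$a_PT, a_m = a_m[i], K = K[i],
                             mu = config$mu, chi = chi[i],
                             vartheta = config$vartheta, X0 = config$X0,
                             units = u)
      sched <- config$schedule[config$schedule <= config$t_end]
      times <- sort(unique(c(seq(0, config$t_end, by = 0.25), sched,
                             config$t_end)))
      tr <- .simulate_on_grid(p, times)
      pt <- cells_to_volume(tr$x_PT[match(sched, times)], u)
      obs <- if (config$sigma > 0)
        pt * exp(rnorm(length(pt), 0, config$sigma)) else pt
      over <- which(obs > config$ceiling_mm3)
      last <- if (length(over)) over[1] else length(obs)
      days <- sched[seq_len(last)]
      endpoint <- days[last]
      if (!length(over)) endpoint <- config$t_end
      endpoints[i] <- endpoint
      srows[[i]] <- data.frame(mouse_id = mid, day = days, site = "PT",
                               volume_mm3 = obs[seq_len(last)],
                               stringsAsFactors = FALSE)
      # endpoint nodules. Only metastases above the detection limit are ever
      # listed, so the process is thinned analytically first: detectable
      # metastases are exactly those born before s* (the birth time whose
      # characteristic reaches the limit by the endpoint), a sub-process
      # with cumulative intensity C_det = N(s*). This keeps memory bounded
      # for aggressive parameter sets that seed millions of micro-metastases.
      iend <- which.min(abs(times - endpoint))
      N_end <- tr$N[iend]; G_end <- tr$G[iend]
      C_det <- if (config$detection_limit_cells <= 1) N_end else {
        G_star <- G_end - log(config$detection_limit_cells) / a_m[i]
        if (G_star <= 0) 0 else {
          s_star <- .monotone_interp(cummax(tr$G), times)(G_star)
          s_star <- min(max(s_star, times[1]), endpoint)
          .monotone_interp(times, cummax(tr$N))(s_star)
        }
      }
      if (config$nodule_sampling == "poisson") {
        count <- rpois(1, C_det)
        qs <- sort(runif(count, 0, C_det))
      } else {
        # zero-noise analog: the expected nodules at their rank quantiles
        count <- floor(C_det)
        qs <- if (count > 0) seq_len(count) - 0.5 else numeric(0)
      }
      if (count > 0) {
        s <- .monotone_interp(cummax(tr$N), times)(qs)
        s <- pmin(pmax(s, times[1]), times[length(times)])
        Gs <- .monotone_interp(times, tr$G)(s)
        size_cells <- exp(a_m[i] * (G_end - Gs))
        size_cells <- size_cells[size_cells >= config$detection_limit_cells]
        if (length(size_cells)) {
          vol <- cells_to_volume(size_cells, u)
          nrows[[length(nrows) + 1]] <- data.frame(
            mouse_id = mid,
            nodule_id = sprintf("%s_n%03d", mid, seq_along(vol)),
            area_mm2 = volume_to_area(vol), volume_mm3 = vol,
            endpoint_day = endpoint, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- data.frame(mouse_id = sprintf("m%02d", seq_len(n)),
                        a_PT = config$a_PT, a_m = a_m, K = K,
                        mu = config$mu, chi = chi,
                        vartheta = config$vartheta, X0 = config$X0,
                        stringsAsFactors = FALSE)
    nods <- if (length(nrows)) nodule_table(do.call(rbind, nrows)) else
      nodule_table(data.frame(mouse_id = character(0),
                              nodule_id = character(0),
                              area_mm2 = numeric(0), volume_mm3 = numeric(0),
                              endpoint_day = numeric(0)))
    names(endpoints) <- sprintf("m%02d", seq_len(n))
    list(series = measurement_series(do.call(rbind, srows)), nodules = nods,
         endpoints = endpoints, truth = truth)
  })
}

#' Write a small canonical fixture bundle
#'
#' Generates and writes the standard fixtures used across the test-suite and
#' examples: one single-tumor mouse, three two-tumor mice (one with a
#' deliberately drifting size ratio, which [ratio_analysis()] must flag),
#' and three metastasis mice (one nodule-free), together with a JSON
#' manifest of the generating parameters. Regeneration with the same seed is
#' byte-identical.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file paths, the datasets and the
#'   manifest.
#' @export
make_fixture_suite <- function(seed = 20260909L, dir = tempfile("fixtures")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- generate_two_tumor_dataset(
    two_tumor_config(n_mice = 1, phi_mean = 0, phi_sd = 0, sigma = 0.03,
                     seed = seed))
  dt <- generate_two_tumor_dataset(
    two_tumor_config(n_mice = 3, sigma = 0.03, seed = seed + 1L))
  # impose a ratio drift on the last DT mouse: T2 decays relative to T1
  dmeas <- dt$measurements
  drift_id <- "m03"
  sel <- dmeas$mouse_id == drift_id & dmeas$site == "T2"
  dmeas$volume_mm3[sel] <- dmeas$volume_mm3[sel] *
    exp(-0.12 * (dmeas$day[sel] - min(dmeas$day[sel])))
  dt$measurements <- measurement_series(dmeas)
  met <- generate_metastatic_dataset(
    metastatic_config(n_mice = 3, sigma = 0.03, seed = seed + 2L,
                      mu = 0.05, a_m_median = 0.04))
  # force one nodule-free mouse for the zero-nodule code paths
  nodfree <- "m03"
  met$nodules <- nodule_table(met$nodules[met$nodules$mouse_id != nodfree, ])

  paths <- list(st = file.path(dir, "st_measurements.csv"),
                dt = file.path(dir, "dt_measurements.csv"),
                met_series = file.path(dir, "met_pt_measurements.csv"),
                met_nodules = file.path(dir, "met_nodules.csv"),
                manifest = file.path(dir, "manifest.json"))
  write_measurements(st$measurements, paths$st)
  write_measurements(dt$measurements, paths$dt)
  write_measurements(met$series, paths$met_series)
  write_nodules(met$nodules, paths$met_nodules)
  manifest <- list(seed = seed, st_truth = st$truth, dt_truth = dt$truth,
                   dt_drift_mouse = drift_id, met_truth = met$truth,
                   met_nodule_free_mouse = nodfree,
                   met_endpoints = as.list(met$endpoints))
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), paths$manifest)
  invisible(list(paths = paths, st = st, dt = dt, met = met,
                 manifest = manifest))
}
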