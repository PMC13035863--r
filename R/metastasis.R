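# Primary tumor + size-structured metastasis population under one shared
# carrying capacity.
#
# The transport equation for the metastasis density rho(x, t),
#   d rho/dt + d(g_m(x, theta) rho)/dx = 0,  g_m = a_m x ln(K / theta),
# with boundary influx B(t) = beta(x_PT, theta) + int beta(x, theta) rho dx
# and beta(x, theta) = mu (1 - theta/K) x^chi, is never discretized in the
# main path. Because g_m is separable, a metastasis born at time s has size
# X(t; s) = exp(a_m (G(t) - G(s))) with G(t) = int_0^t ln(K/theta) du, and the
# population collapses exactly to the augmented ODE system integrated in C++
# (see src/solver.cpp). The direct upwind discretization lives in
# pde_oracle_simulate() as an independent check.

#' Parameters of the shared-capacity metastasis model
#'
#' @param a_PT intrinsic growth rate of the primary tumor, per day.
#' @param a_m intrinsic growth rate of the metastases, per day.
#' @param K shared carrying capacity in mm^3 (converted to cells internally).
#' @param mu per-cell per-day metastatic seeding coefficient.
#' @param chi fractal dimension in [0, 1]: the exponent with which a tumor's
#'   seeding propensity scales with its size in cells.
#' @param vartheta fraction of inoculated cells that establish the primary
#'   tumor, in [0, 1].
#' @param X0 inoculated volume in mm^3; the primary starts at
#'   `vartheta * X0`.
#' @param units a [unit_convention()].
#' @return object of class `metastatic_params`.
#' @examples
#' # the Py230-C57BL/6 "mouse 9" parameter set
#' metastatic_params(a_PT = 0.032, a_m = 0.032, K = 5000, mu = 0.016,
#'                   chi = 0.400, vartheta = 0.011, X0 = 3)
#' @export
metastatic_params <- function(a_PT, a_m, K, mu, chi, vartheta, X0,
                              units = unit_convention()) {
  stopifnot(inherits(units, "unit_convention"))
  if (any(c(a_PT, a_m, K, mu) < 0)) stop("rates and capacity must be non-negative")
  if (chi < 0 || chi > 1) stop("`chi` must lie in [0, 1]")
  if (vartheta < 0 || vartheta > 1) stop("`vartheta` must lie in [0, 1]")
  if (X0 <= 0) stop("`X0` must be positive")
  if (K <= 0) stop("`K` must be positive")
  structure(list(a_PT = a_PT, a_m = a_m, K = K, mu = mu, chi = chi,
                 vartheta = vartheta, X0 = X0, units = units),
            class = "metastatic_params")
}

#' Intervention specification for counterfactual simulations
#'
#' `surgery_time` schedules removal of the primary tumor. Two surgery
#' semantics are available: `"arrest"` stops the primary's growth and seeding
#' but leaves its capacity footprint in the shared burden (the resection bed
#' keeps the host resources it had recruited); `"resect"` removes the
#' primary's mass from the burden instantly, so the per-metastasis relative
#' growth rate `a_m ln(K/theta)` jumps upward at the event. `"arrest"` is the
#' default because it reproduces the published counterfactual counts; see the
#' methods vignette for the full comparison.
#'
#' @param surgery_time day of surgery, or `NA` for none.
#' @param surgery_mode `"arrest"` or `"resect"`.
#' @param seeding_off if `TRUE`, sets the seeding coefficient mu to zero for
#'   the whole simulation (the inhibited-seeding counterfactual).
#' @return object of class `intervention_spec`.
#' @export
intervention <- function(surgery_time = NA_real_,
                         surgery_mode = c("arrest", "resect"),
                         seeding_off = FALSE) {
  surgery_mode <- match.arg(surgery_mode)
  if (!is.na(surgery_time) && surgery_time < 0)
    stop("`surgery_time` must be non-negative")
  structure(list(surgery_time = surgery_time, surgery_mode = surgery_mode,
                 seeding_off = isTRUE(seeding_off)),
            class = "intervention_spec")
}

#' Metastatic seeding rate
#'
#' `beta(x, theta) = mu * max(0, 1 - theta/K) * x^chi`: the rate at which a
#' tumor of `x` cells seeds new metastases given total burden `theta`. It
#' vanishes when the burden reaches the shared capacity and, by convention,
#' `0^chi = 0` for every `chi` (a removed tumor seeds nothing).
#'
#' @param x tumor size in cells (>= 0).
#' @param theta total tumor burden in cells (>= 0).
#' @param params a [metastatic_params()].
#' @return seeding rate, metastases per day.
#' @export
seeding_rate <- function(x, theta, params) {
  stopifnot(inherits(params, "metastatic_params"))
  if (any(x < 0) || any(theta < 0)) stop("`x` and `theta` must be non-negative")
  K_cells <- volume_to_cells(params$K, params$units)
  ifelse(x > 0,
         params$mu * pmax(0, 1 - theta / K_cells) * x^params$chi,
         0)
}

#' Simulate the shared-capacity metastasis model
#'
#' Integrates the exact characteristics/renewal reduction of the transport
#' model: primary size, the relative-growth integral
#' `G(t) = int_0^t ln(K/theta) du`, the metastatic burden, the seeding moment
#' and the cumulative seeded count, with the seeding rate recovered
#' algebraically. Surgery is handled as an integration event at
#' `surgery_time` (see [intervention()] for the two semantics).
#'
#' @param params a [metastatic_params()].
#' @param t_end final day (> 0).
#' @param intervention an [intervention()]; default none.
#' @param dt output grid spacing in days (the integration itself is adaptive).
#' @param rtol,atol solver tolerances.
#' @return object of class `metastatic_trajectory`: a list with `times`,
#'   `x_PT` (primary, cells), `theta` (total burden, cells), `B` (seeding
#'   rate per day), `G`, `N` (cumulative seeded count), `M` (metastatic
#'   burden, cells), plus the parameters and intervention.
#' @examples
#' p <- metastatic_params(0.032, 0.032, 5000, 0.016, 0.4, 0.011, 3)
#' tr <- simulate_metastatic(p, t_end = 59,
#'                           intervention = intervention(surgery_time = 35))
#' count_above(tr, t = 59, threshold = 3500)
#' @export
simulate_metastatic <- function(params, t_end,
                                intervention = sharedcap::intervention(),
                                dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "metastatic_params"),
            inherits(intervention, "intervention_spec"))
  if (t_end <= 0) stop("`t_end` must be positive")
  st <- intervention$surgery_time
  if (!is.na(st) && st >= t_end)
    stop("`surgery_time` must lie within the simulation span")
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  # the surgery day itself must be on the grid so post-event values are exact
  if (!is.na(st) && !any(abs(times - st) < 1e-12))
    times <- sort(c(times, st))

  u <- params$units
  K_cells <- volume_to_cells(params$K, u)
  x0 <- params$vartheta * volume_to_cells(params$X0, u)
  if (x0 <= 0) stop("initial primary size vartheta * X0 must be positive")
  mu <- if (intervention$seeding_off) 0 else params$mu
  mode <- if (is.na(st)) 0L else match(intervention$surgery_mode,
                                       c("resect", "arrest"))
  m <- cpp_simulate_metastatic(params$a_PT, params$a_m, K_cells, mu,
                               params$chi, x0, times,
                               if (is.na(st)) NA_real_ else st,
                               mode, rtol, atol)
  structure(list(times = times, x_PT = m[, "x_PT"], theta = m[, "theta"],
                 B = m[, "B"], G = m[, "G"], N = m[, "N"], M = m[, "M"],
                 params = params, intervention = intervention),
            class = "metastatic_trajectory")
}

#' @export
print.metastatic_trajectory <- function(x, ...) {
  n <- length(x$times)
  u <- x$params$units
  cat(sprintf("<metastatic_trajectory> t in [0, %g] d, %d points\n",
              max(x$times), n))
  cat(sprintf("  primary: %.3g mm^3, burden theta: %.3g mm^3, seeded N: %.1f\n",
              cells_to_volume(x$x_PT[n], u), cells_to_volume(x$theta[n], u),
              x$N[n]))
  if (!is.na(x$intervention$surgery_time))
    cat(sprintf("  surgery (%s) at day %g\n", x$intervention$surgery_mode,
                x$intervention$surgery_time))
  invisible(x)
}

#' @export
as.data.frame.metastatic_trajectory <- function(x, ...) {
  u <- x$params$units
  data.frame(time = x$times,
             x_PT_mm3 = cells_to_volume(x$x_PT, u),
             theta_mm3 = cells_to_volume(x$theta, u),
             B_per_day = x$B, N = x$N, G = x$G)
}

# monotone interpolants of G(t) and N(t); G is strictly increasing while
# theta < K, so the inverse is well defined. Hyman-filtered cubic keeps
# monotonicity.
# monotone interpolant of y(x) usable as an inverse: Hyman-filtered cubic
# when x is strictly increasing, last-crossing linear otherwise
.monotone_interp <- function(x, y) {
  if (all(diff(x) > 0)) {
    splinefun(x, y, method = "hyman")
  } else {
    function(q) approx(x, y, xout = q, ties = max, rule = 2)$y
  }
}

.traj_interp <- function(traj) {
  Gm <- cummax(traj$G)
  # with a pathological theta >= K, G stalls; fall back to a linear inverse
  # that picks the last crossing
  Ginv <- if (all(diff(Gm) > 0)) {
    splinefun(Gm, traj$times, method = "hyman")
  } else {
    function(g) approx(Gm, traj$times, xout = g, ties = max, rule = 2)$y
  }
  list(G = splinefun(traj$times, traj$G, method = "hyman"),
       N = splinefun(traj$times, cummax(traj$N), method = "hyman"),
       Ginv = Ginv)
}

.check_in_span <- function(traj, t) {
  if (any(t < min(traj$times) - 1e-9) || any(t > max(traj$times) + 1e-9))
    stop("time outside the simulated span")
}

#' Size of a metastasis born at a given time
#'
#' A metastasis enters at cell size one and grows along the characteristic
#' `X(t; s) = exp(a_m (G(t) - G(s)))`.
#'
#' @param traj a `metastatic_trajectory`.
#' @param birth_time birth day(s) `s`.
#' @param t evaluation day, `birth_time <= t`.
#' @return size(s) in cells.
#' @export
metastasis_size <- function(traj, birth_time, t) {
  stopifnot(inherits(traj, "metastatic_trajectory"))
  .check_in_span(traj, c(birth_time, t))
  if (any(birth_time > t)) stop("`birth_time` must not exceed `t`")
  ip <- .traj_interp(traj)
  exp(traj$params$a_m * (ip$G(t) - ip$G(birth_time)))
}

#' Count metastases at or above a size threshold
#'
#' Metastases born earlier are larger, so the number of metastases of at
#' least `threshold` cells at time `t` equals `N(s*)`, where `s*` is the
#' latest birth time satisfying `a_m (G(t) - G(s*)) >= ln(threshold)`. The
#' inversion uses monotone cubic interpolation of `G`. The continuous count
#' is returned along with its nearest-integer rounding, which is how counts
#' are reported.
#'
#' @param traj a `metastatic_trajectory`.
#' @param t evaluation day.
#' @param threshold size threshold in cells (>= 1); by default the unit
#'   convention's clinical relevance threshold.
#' @return list with `count` (rounded) and `raw` (continuous).
#' @export
count_above <- function(traj, t,
                        threshold = traj$params$units$relevance_threshold_cells) {
  stopifnot(inherits(traj, "metastatic_trajectory"))
  if (threshold < 1) stop("`threshold` must be at least 1 cell")
  .check_in_span(traj, t)
  raw <- .count_above_raw(traj, t, threshold)
  list(count = round(raw), raw = raw)
}

.count_above_raw <- function(traj, t, threshold) {
  ip <- .traj_interp(traj)
  a_m <- traj$params$a_m
  vapply(threshold, function(thr) {
    if (thr <= 1) return(ip$N(t))        # every seeded metastasis counts
    if (a_m <= 0) return(0)              # nothing ever grows past 1 cell
    Gstar <- ip$G(t) - log(thr) / a_m
    if (Gstar <= 0) return(0)            # not even a day-0 metastasis is big enough
    sstar <- min(ip$Ginv(Gstar), t)
    ip$N(sstar)
  }, numeric(1))
}

#' Cumulative size distribution of the metastases
#'
#' For each size on the grid, the (continuous) number of metastases at least
#' that large at time `t`; nonincreasing in size by construction.
#'
#' @param traj a `metastatic_trajectory`.
#' @param t evaluation day.
#' @param size_grid sizes in cells (>= 1), increasing.
#' @return object of class `size_distribution`: data.frame with
#'   `size_cells`, `size_mm3`, `cumulative_count`.
#' @export
cumulative_size_distribution <- function(traj, t, size_grid) {
  stopifnot(inherits(traj, "metastatic_trajectory"))
  if (length(size_grid) == 0) stop("`size_grid` must not be empty")
  if (any(size_grid < 1)) stop("sizes below one cell are not meaningful")
  .check_in_span(traj, t)
  cnt <- .count_above_raw(traj, t, size_grid)
  out <- data.frame(size_cells = size_grid,
                    size_mm3 = cells_to_volume(size_grid, traj$params$units),
                    cumulative_count = cnt)
  class(out) <- c("size_distribution", class(out))
  out
}
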