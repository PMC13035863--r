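# Direct discretization of the metastasis transport equation, used as an
# independent oracle for the characteristics reduction in
# simulate_metastatic(). Deliberately simple and first-order: conservative
# donor-cell upwind fluxes on a log-spaced size grid, forward Euler in time
# with a CFL-limited step, and the primary integrated alongside with the same
# steps. Accuracy is traded for independence; agreement within a few percent
# and first-order grid convergence are what the tests assert.

#' Upwind finite-volume oracle for the metastasis model
#'
#' Solves the size-structured transport equation for the metastasis density
#' directly on a log-spaced size grid `[1, x_max]` with conservative
#' first-order upwind fluxes, the boundary influx
#' `g(1, theta) rho(1, t) = beta(x_PT, theta) + int beta(x, theta) rho dx`,
#' and forward Euler time stepping at a fixed fraction of the CFL limit.
#' Used to verify [simulate_metastatic()]; it is orders of magnitude slower
#' and should only be run on small instances.
#'
#' @param params a [metastatic_params()].
#' @param t_end final day.
#' @param n_cells number of finite-volume cells in size.
#' @param x_max upper end of the size grid in cells; must exceed the largest
#'   metastasis reached by `t_end` (the function stops if outflow through the
#'   top boundary becomes noticeable).
#' @param intervention an [intervention()].
#' @param cfl Courant number in (0, 1].
#' @param n_out number of output times.
#' @return list with `times`, `x_PT`, `theta`, `N` (all as in
#'   [simulate_metastatic()]), plus `edges`, `centers` and the final density
#'   `rho` (per-cell counts / cell width) for distribution checks.
#' @export
pde_oracle_simulate <- function(params, t_end, n_cells = 400, x_max = 1e6,
                                intervention = sharedcap::intervention(),
                                cfl = 0.5, n_out = 200) {
  stopifnot(inherits(params, "metastatic_params"),
            inherits(intervention, "intervention_spec"))
  if (cfl <= 0 || cfl > 1) stop("`cfl` must be in (0, 1]")
  u <- params$units
  K <- volume_to_cells(params$K, u)
  x0 <- params$vartheta * volume_to_cells(params$X0, u)
  a_PT <- params$a_PT; a_m <- params$a_m; chi <- params$chi
  mu <- if (intervention$seeding_off) 0 else params$mu
  st <- intervention$surgery_time
  resect <- !is.na(st) && intervention$surgery_mode == "resect"
  arrest <- !is.na(st) && intervention$surgery_mode == "arrest"

  edges <- exp(seq(0, log(x_max), length.out = n_cells + 1))
  centers <- sqrt(edges[-1] * edges[-(n_cells + 1)])
  dx <- diff(edges)

  # CFL for g = a_m x ln(K/theta): on a log grid dt <= cfl * dlog(x) / (a_m L).
  # After a resection the burden can drop to a few cells, so bound the
  # relative growth rate by its absolute worst case log(K).
  Lmax <- log(K)
  dlog <- min(diff(log(edges)))
  dt <- cfl * dlog / max(a_m * Lmax, 1e-12)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps

  rho <- numeric(n_cells)          # density: count per unit size
  x <- x0
  N <- 0
  primary_on <- TRUE

  t_out <- seq(0, t_end, length.out = n_out)
  out <- matrix(NA_real_, n_out, 4,
                dimnames = list(NULL, c("time", "x_PT", "theta", "N")))
  k_out <- 1L

  record <- function(t) {
    theta <- x + sum(centers * rho * dx)
    out[k_out, ] <<- c(t, x, theta, N)
    k_out <<- k_out + 1L
  }
  record(0)

  t <- 0
  for (step in seq_len(nsteps)) {
    theta <- x + sum(centers * rho * dx)
    L <- log(K / max(theta, 1e-12))
    supp <- max(0, 1 - theta / K)
    seed_primary <- if (primary_on && x > 0) mu * supp * x^chi else 0
    B <- seed_primary + mu * supp * sum(centers^chi * rho * dx)

    # conservative upwind: flux through interior edge j+1 is g(edge) * rho_j
    g_edges <- a_m * edges * L
    if (L < 0) stop("oracle assumes theta < K throughout (CFL setup)")
    flux <- c(B, g_edges[2:(n_cells + 1)] * rho)  # influx at x = 1
    if (flux[n_cells + 1] * dt > 1e-6 * max(N, 1))
      stop("size grid too small: noticeable outflow at x_max; raise `x_max`")
    rho <- rho + dt * (flux[1:n_cells] - flux[2:(n_cells + 1)]) / dx
    N <- N + dt * B
    if (primary_on && x > 0) x <- x + dt * a_PT * x * L
    t <- t + dt

    # surgery between this step and the next
    if (!is.na(st) && t - dt < st && t >= st) {
      if (resect) x <- 0 else primary_on <- FALSE
    }
    while (k_out <= n_out && t_out[k_out] <= t + 1e-12) record(t_out[k_out])
  }
  while (k_out <= n_out) record(t_out[k_out])

  theta_end <- x + sum(centers * rho * dx)
  list(times = out[, "time"], x_PT = out[, "x_PT"], theta = out[, "theta"],
       N = out[, "N"], edges = edges, centers = centers, rho = rho,
       count_above = function(s) sum((rho * dx)[centers >= s]),
       theta_end = theta_end, N_end = N)
}
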