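# Particle swarm optimization. Self-contained, seeded and deterministic:
# constriction-style coefficients, reflecting bounds, optional restarts
# keeping the best swarm.

#' Optimizer configuration for particle swarm fits
#'
#' Defaults follow the common constriction parameterization (inertia 0.729,
#' cognitive = social = 1.49445) with 50 particles, 300 iterations and 3
#' restarts; all overridable. Every stochastic draw derives from `seed`, so a
#' fit is bit-reproducible given (data, model, config).
#'
#' @param swarm_size particles per swarm.
#' @param max_iterations iterations per restart.
#' @param inertia,cognitive,social velocity update coefficients.
#' @param restarts independent swarms; the best result is kept.
#' @param seed integer seed.
#' @param stall_iterations stop a swarm early after this many iterations
#'   without improvement of the best objective by `stall_tol` (relative).
#' @param stall_tol relative improvement threshold for the stall check.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(swarm_size = 50, max_iterations = 300,
                             inertia = 0.729, cognitive = 1.49445,
                             social = 1.49445, restarts = 3, seed = 1L,
                             stall_iterations = 75, stall_tol = 1e-10) {
  stopifnot(swarm_size >= 2, max_iterations >= 1, restarts >= 1)
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 stall_iterations = as.integer(stall_iterations),
                 stall_tol = stall_tol),
            class = "optimizer_config")
}

#' Minimize an objective with particle swarm optimization
#'
#' Box-constrained global minimization. Positions are initialized uniformly
#' in the box, velocities at a fraction of the box width; particles leaving
#' the box are reflected. Non-finite objective values are treated as +Inf
#' penalties. The caller's RNG state is left untouched.
#'
#' @param objective function of a numeric parameter vector returning a scalar.
#' @param lower,upper finite bounds, equal length.
#' @param config an [optimizer_config()].
#' @param init optional matrix (or vector) of initial positions; rows are
#'   clamped to the box and replace the first particles of the first swarm.
#'   Used to seed a fit with problem-specific starting guesses.
#' @return list with `par`, `value`, `history` (best value per iteration,
#'   concatenated over restarts), `evaluations` and `converged` (`TRUE`
#'   unless every evaluation was non-finite).
#' @examples
#' pso_minimize(function(p) sum(p^2), c(-5, -5), c(5, 5),
#'              optimizer_config(swarm_size = 20, max_iterations = 50))
#' @export
pso_minimize <- function(objective, lower, upper, config = optimizer_config(),
                         init = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  d <- length(lower)
  if (length(upper) != d || d == 0) stop("`lower` and `upper` lengths differ")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper")

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv()) else old_seed <- NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  span <- upper - lower
  eval_pen <- function(p) {
    v <- tryCatch(objective(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  best_par <- NULL; best_val <- Inf
  history <- numeric(0); nev <- 0L

  for (rs in seq_len(config$restarts)) {
    X <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
    X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
    if (rs == 1L && !is.null(init)) {
      ini <- matrix(init, ncol = d)
      k <- min(nrow(ini), config$swarm_size)
      for (i in seq_len(k))
        X[i, ] <- pmin(pmax(ini[i, ], lower), upper)
    }
    if (rs > 1L && !is.null(best_par)) X[1, ] <- best_par
    V <- matrix(runif(config$swarm_size * d, -1, 1), config$swarm_size, d)
    V <- sweep(V, 2, span * 0.1, "*")

    f <- apply(X, 1, eval_pen); nev <- nev + nrow(X)
    Pb <- X; fPb <- f
    g <- which.min(f)
    stall <- 0L; swarm_best <- f[g]

    for (it in seq_len(config$max_iterations)) {
      R1 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      R2 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      Gb <- matrix(Pb[g, ], config$swarm_size, d, byrow = TRUE)
      V <- config$inertia * V +
        config$cognitive * R1 * (Pb - X) +
        config$social * R2 * (Gb - X)
      X <- X + V
      # reflect at the box and damp the velocity component
      for (j in seq_len(d)) {
        lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
        X[lo, j] <- 2 * lower[j] - X[lo, j]; V[lo, j] <- -0.5 * V[lo, j]
        X[hi, j] <- 2 * upper[j] - X[hi, j]; V[hi, j] <- -0.5 * V[hi, j]
        X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
      }
      f <- apply(X, 1, eval_pen); nev <- nev + nrow(X)
      imp <- f < fPb
      Pb[imp, ] <- X[imp, ]; fPb[imp] <- f[imp]
      g <- which.min(fPb)
      history <- c(history, fPb[g])
      if (fPb[g] < swarm_best * (1 - config$stall_tol) ||
          (swarm_best == Inf && is.finite(fPb[g]))) {
        swarm_best <- fPb[g]; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$stall_iterations) break
    }
    if (fPb[g] < best_val) { best_val <- fPb[g]; best_par <- Pb[g, ] }
  }

  if (!is.finite(best_val))
    stop("pso_minimize: objective was non-finite everywhere it was evaluated")
  list(par = as.numeric(best_par), value = best_val, history = history,
       evaluations = nev, converged = is.finite(best_val))
}
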