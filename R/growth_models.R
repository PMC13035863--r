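# Single and coupled two-tumor growth laws: closed forms + ODE simulation.

.laws <- c("gompertz", "logistic", "exponential")
.capacity_modes <- c("shared", "individual_equal", "individual_unequal")

#' Growth law specification
#'
#' @param law one of `"gompertz"`, `"logistic"`, `"exponential"`. The
#'   exponential law has no carrying capacity parameter.
#' @return object of class `growth_law`.
#' @export
growth_law <- function(law = c("gompertz", "logistic", "exponential")) {
  law <- match.arg(law)
  structure(list(law = law), class = "growth_law")
}

.law_code <- function(law) {
  if (inherits(law, "growth_law")) law <- law$law
  match(match.arg(law, .laws), .laws) - 1L
}

#' Closed-form growth curves
#'
#' Exact solutions of the three single-tumor growth laws:
#' Gompertz `dT/dt = r T ln(K/T)` gives `T(t) = K exp(ln(T0/K) exp(-r t))`;
#' logistic `dT/dt = r T (1 - T/K)` gives the standard sigmoid; the
#' exponential law gives `T0 exp(r t)`.
#'
#' @param T0 initial volume (> 0), same unit as `K`.
#' @param r intrinsic growth rate per day (>= 0).
#' @param K carrying capacity (> 0).
#' @param t time(s) in days (>= 0); vectorized.
#' @return volume(s) at `t`.
#' @examples
#' gompertz_closed_form(1, 0.085, 7740, 10)
#' logistic_closed_form(50, 0.1, 100, log(3) / 0.1)  # 75
#' @export
gompertz_closed_form <- function(T0, r, K, t) {
  if (any(T0 <= 0)) stop("`T0` must be positive")
  if (any(K <= 0)) stop("`K` must be positive")
  if (any(r < 0)) stop("`r` must be non-negative")
  K * exp(log(T0 / K) * exp(-r * t))
}

#' @rdname gompertz_closed_form
#' @export
logistic_closed_form <- function(T0, r, K, t) {
  if (any(T0 <= 0)) stop("`T0` must be positive")
  if (any(K <= 0)) stop("`K` must be positive")
  if (any(r < 0)) stop("`r` must be non-negative")
  K / (1 + (K / T0 - 1) * exp(-r * t))
}

#' @rdname gompertz_closed_form
#' @export
exponential_closed_form <- function(T0, r, t) {
  if (any(T0 <= 0)) stop("`T0` must be positive")
  T0 * exp(r * t)
}

#' Parameters of the coupled two-tumor system
#'
#' Describes two tumors growing simultaneously in one host. Under
#' `capacity_mode = "shared"` both tumors decelerate with their combined
#' burden (`ln(K / (T1 + T2))` for Gompertz); under the individual modes each
#' tumor sees only its own capacity. `T1` denotes the larger tumor; the
#' initial sizes may be given either as `(T1_0, T2_0)` or as `(T1_0, phi)`
#' with `phi = T2_0 / T1_0` in [0, 1].
#'
#' @param r1,r2 intrinsic growth rates, per day.
#' @param capacity_mode `"shared"`, `"individual_equal"` or
#'   `"individual_unequal"`.
#' @param K shared capacity (mm^3), for `"shared"` and `"individual_equal"`.
#' @param K1,K2 individual capacities, for `"individual_unequal"`.
#' @param T1_0 initial volume of the larger tumor (mm^3).
#' @param T2_0 initial volume of the smaller tumor; mutually exclusive with
#'   `phi`.
#' @param phi initial size ratio `T2_0 / T1_0` in [0, 1].
#' @return object of class `two_tumor_params`.
#' @export
two_tumor_params <- function(r1, r2 = r1,
                             capacity_mode = c("shared", "individual_equal",
                                               "individual_unequal"),
                             K = NULL, K1 = NULL, K2 = NULL,
                             T1_0 = 1, T2_0 = NULL, phi = NULL) {
  capacity_mode <- match.arg(capacity_mode)
  if (r1 <= 0 || r2 <= 0) stop("growth rates must be positive")
  if (T1_0 <= 0) stop("`T1_0` must be positive (use T2_0 = 0 for a single tumor)")
  if (!is.null(T2_0) && !is.null(phi))
    stop("give either `T2_0` or `phi`, not both")
  if (is.null(T2_0)) T2_0 <- if (is.null(phi)) 0 else phi * T1_0
  if (T2_0 < 0) stop("`T2_0` must be non-negative")
  if (T2_0 > T1_0) stop("`T1` denotes the larger tumor: need T1_0 >= T2_0")
  if (capacity_mode == "individual_unequal") {
    if (is.null(K1) || is.null(K2)) stop("individual_unequal needs `K1` and `K2`")
    if (K1 <= 0 || K2 <= 0) stop("capacities must be positive")
    K <- NULL
  } else {
    if (is.null(K)) stop(sprintf("capacity_mode '%s' needs `K`", capacity_mode))
    if (K <= 0) stop("capacities must be positive")
    K1 <- K2 <- K
  }
  structure(list(r1 = r1, r2 = r2, capacity_mode = capacity_mode, K = K,
                 K1 = K1, K2 = K2, T1_0 = T1_0, T2_0 = T2_0,
                 phi = T2_0 / T1_0),
            class = "two_tumor_params")
}

.new_trajectory <- function(times, T1, T2) {
  structure(list(times = times, T1 = T1, T2 = T2), class = "tumor_trajectory")
}

#' @export
as.data.frame.tumor_trajectory <- function(x, ...) {
  data.frame(time = x$times, T1 = x$T1, T2 = x$T2)
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf("<tumor_trajectory> %d time points, t in [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  T1: %g -> %g; T2: %g -> %g\n",
              x$T1[1], x$T1[length(x$T1)], x$T2[1], x$T2[length(x$T2)]))
  invisible(x)
}

#' Simulate a single tumor
#'
#' Numerically integrates the chosen growth law on a time grid with an
#' adaptive Dormand-Prince RK45 scheme (relative/absolute tolerances 1e-8 /
#' 1e-10 by default). For the Gompertz and logistic laws the result agrees
#' with the closed form to the integration tolerance.
#'
#' @param law a [growth_law()] or law name.
#' @param T0 initial volume (> 0).
#' @param r intrinsic growth rate, per day.
#' @param K carrying capacity; ignored for the exponential law.
#' @param times strictly increasing time grid (days).
#' @param rtol,atol solver tolerances.
#' @return a `tumor_trajectory` (with `T2` identically zero).
#' @export
simulate_single <- function(law, T0, r, K = NULL, times,
                            rtol = 1e-8, atol = 1e-10) {
  code <- .law_code(law)
  .check_times(times)
  if (T0 <= 0) stop("`T0` must be positive")
  if (code != 2L && (is.null(K) || K <= 0))
    stop("this law needs a positive carrying capacity `K`")
  if (code == 2L) K <- 1  # unused
  m <- cpp_simulate_two_tumor(code, r, r, K, K, TRUE, T0, 0, times, rtol, atol)
  .new_trajectory(times, m[, "T1"], m[, "T2"])
}

#' Simulate the coupled two-tumor system
#'
#' Integrates two tumors under the chosen law. With a shared capacity the
#' coupling is through the combined burden; with individual capacities the
#' tumors grow independently. A tumor initialized at exactly zero stays at
#' zero, so `T2_0 = 0` reduces the system to a one-tumor growth law.
#'
#' @param law a [growth_law()] or law name.
#' @param params a [two_tumor_params()].
#' @inheritParams simulate_single
#' @return a `tumor_trajectory`.
#' @examples
#' p <- two_tumor_params(r1 = 0.085, K = 7740, T1_0 = 1, phi = 0.5)
#' tr <- simulate_two_tumor("gompertz", p, times = 0:25)
#' @export
simulate_two_tumor <- function(law, params, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "two_tumor_params"))
  code <- .law_code(law)
  .check_times(times)
  shared <- params$capacity_mode == "shared"
  m <- cpp_simulate_two_tumor(code, params$r1, params$r2, params$K1,
                              params$K2, shared, params$T1_0, params$T2_0,
                              times, rtol, atol)
  .new_trajectory(times, m[, "T1"], m[, "T2"])
}

.check_times <- function(times) {
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("`times` must be a strictly increasing grid with at least 2 points")
  if (any(times < 0)) stop("`times` must be non-negative")
  invisible(times)
}
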