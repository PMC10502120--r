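#' Closed-form solution of the logistic growth equation
#'
#' Evaluates \eqn{x(t) = x_0 K e^{rt} / ((K - x_0) + x_0 e^{rt})} on a
#' vector of times.  The expression is evaluated in the rearranged form
#' \eqn{K / (1 + ((K - x_0)/x_0) e^{-rt})} so that the exponential never
#' overflows for large `r * t`.
#'
#' For `0 < x0 < K` the curve is strictly increasing with `0 < x(t) < K`;
#' for `x0 > K` it decreases monotonically toward `K`.  Negative times are
#' permitted (the closed form extends the curve backwards).
#'
#' @param params A [growth_params()] object.
#' @param times Numeric vector of (finite) times.
#' @return Numeric vector of abundances, one per time.
#' @examples
#' gp <- growth_params(1.2, 100, 1)
#' logistic_solution(gp, log(99) / 1.2)  # the midpoint K/2
#' @export
logistic_solution <- function(params, times) {
  params <- as_growth_params(params)
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    stop("logistic_solution: 'times' must be finite numeric", call. = FALSE)
  }
  A <- (params$K - params$x0) / params$x0
  params$K / (1 + A * exp(-params$r * times))
}

#' First derivative (effective growth rate) of the logistic curve
#'
#' Returns \eqn{dx/dt = r x (1 - x/K)} evaluated on the closed-form
#' solution.  Non-negative for `0 < x0 < K`, maximal (`rK/4`) where the
#' abundance crosses `K/2`.
#'
#' @inheritParams logistic_solution
#' @return Numeric vector of growth rates.
#' @export
logistic_rate <- function(params, times) {
  params <- as_growth_params(params)
  x <- logistic_solution(params, times)
  params$r * x * (1 - x / params$K)
}

#' Second derivative (growth acceleration) of the logistic curve
#'
#' Returns \eqn{d^2x/dt^2 = r^2 x (1 - x/K)(1 - 2x/K)} evaluated on the
#' closed-form solution: positive before the abundance reaches `K/2`,
#' zero at `K/2`, negative after, with a single peak and a single trough.
#'
#' The `r^2` prefactor is the analytically exact second derivative
#' (differentiate \eqn{r x (1 - x/K)} once more by the chain rule).  Any
#' positive prefactor gives the same geometry up to scale, and the phase
#' boundaries derived from this curve ([phase_boundaries()]) are provably
#' invariant to it; `prefactor` is exposed so that invariance can be
#' exercised directly.
#'
#' @inheritParams logistic_solution
#' @param prefactor Positive scale for the curve; defaults to `r^2`.
#' @return Numeric vector of accelerations.
#' @export
logistic_acceleration <- function(params, times, prefactor = NULL) {
  params <- as_growth_params(params)
  if (is.null(prefactor)) prefactor <- params$r^2
  if (!is.numeric(prefactor) || length(prefactor) != 1L || prefactor <= 0) {
    stop("logistic_acceleration: 'prefactor' must be a single positive number",
         call. = FALSE)
  }
  x <- logistic_solution(params, times)
  u <- x / params$K
  prefactor * x * (1 - u) * (1 - 2 * u)
}

# Time at which the curve passes abundance x (inverse of the solution),
# measured from the curve origin (t = 0 at x = x0).
logistic_time_of <- function(params, x) {
  log(x * (params$K - params$x0) / (params$x0 * (params$K - x))) / params$r
}

# Scaled acceleration shape f(u) = u (1 - u)(1 - 2u) on u = x/K in (0, 1).
# Peak at u = (3 - sqrt(3))/6, trough at u = (3 + sqrt(3))/6; the crossing
# abundances of any half-max/half-min level are roots of f and do not
# depend on r, K or the prefactor.
accel_shape <- function(u) u * (1 - u) * (1 - 2 * u)

#' Growth-phase boundaries from the acceleration curve
#'
#' Computes the four boundary times `s1 < s2 < s3 < s4` that delimit the
#' growth phases of a logistic curve: `s1`, `s2` are the two times where
#' the acceleration (second derivative) crosses half of its maximum,
#' bracketing the acceleration peak, and `s3`, `s4` are the two times
#' where it crosses half of its minimum, bracketing the deceleration
#' trough.  The resulting windows are: lag+acceleration `t < s2`, mid-log
#' `s2 <= t < s3`, deceleration `s3 <= t < s4`, stationary `t >= s4`
#' (lag is folded into acceleration; see [assign_phase()]).
#'
#' Roots are found by bracketed root-finding on `t`, with brackets derived
#' from the analytic crossing abundances (the crossings of the scaled
#' shape `u(1-u)(1-2u)`, which depend on neither `r`, `K` nor the
#' prefactor).  Convergence is verified to `|f| < 1e-10 * a_peak`.
#' `s1` may be negative when the curve starts above the first crossing
#' abundance (the closed form extends backwards in time).
#'
#' @param params A [growth_params()] object with `0 < x0 < K/2` (curves
#'   starting at or beyond the acceleration zero-crossing have no
#'   complete set of forward crossings and are refused).
#' @param t0 Time at which the curve starts (`x(t0) = x0`); boundary
#'   times are reported on this absolute axis.  Default 0.
#' @param prefactor Positive scale of the acceleration curve (see
#'   [logistic_acceleration()]); the boundary times do not depend on it.
#' @return An object of class `"phase_boundaries"`: a list with `s1`,
#'   `s2`, `s3`, `s4`, the acceleration extremes `a_peak`, `a_trough`,
#'   the crossing levels `a_halfmax`, `a_halfmin`, plus `params` and `t0`.
#' @examples
#' b <- phase_boundaries(growth_params(1.2, 100, 1))
#' b$s1 < b$s2  # acceleration window precedes mid-log
#' assign_phase(c(1, 4, 5, 10), b)
#' @export
phase_boundaries <- function(params, t0 = 0, prefactor = NULL) {
  params <- as_growth_params(params)
  if (params$x0 >= params$K / 2) {
    stop("phase_boundaries: x0 >= K/2 - the curve starts past the ",
         "acceleration peak, so the half-max crossings s1/s2 do not ",
         "exist on the forward curve", call. = FALSE)
  }
  if (is.null(prefactor)) prefactor <- params$r^2
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))

  u_peak <- (3 - sqrt(3)) / 6
  u_trough <- (3 + sqrt(3)) / 6
  a_peak <- prefactor * params$K * accel_shape(u_peak)
  a_trough <- prefactor * params$K * accel_shape(u_trough)

  # crossing abundances: roots of f(u) = f(u_extreme)/2 in the four
  # sub-intervals delimited by the extremes and the zero at u = 1/2
  half <- accel_shape(u_peak) / 2          # = -accel_shape(u_trough)/2
  u_root <- function(lo, hi, level) {
    stats::uniroot(function(u) accel_shape(u) - level, c(lo, hi),
                   tol = .Machine$double.eps^0.75)$root
  }
  eps <- 1e-12
  u1 <- u_root(eps, u_peak, half)
  u2 <- u_root(u_peak, 0.5, half)
  u3 <- u_root(0.5, u_trough, -half)
  u4 <- u_root(u_trough, 1 - eps, -half)

  # refine on the time axis with brackets from the analytic abundances
  accel_t <- function(t) {
    logistic_acceleration(params, t, prefactor = prefactor)
  }
  t_of_u <- function(u) logistic_time_of(params, u * params$K)
  refine <- function(u, level, name) {
    t_guess <- t_of_u(u)
    w <- max(0.5 / params$r, 1e-3)
    f <- function(t) accel_t(t) - level
    lo <- t_guess - w
    hi <- t_guess + w
    while (sign(f(lo)) == sign(f(hi))) {   # widen until bracketed
      lo <- lo - w
      hi <- hi + w
      if (hi - lo > 1e6) {
        stop("phase_boundaries: failed to bracket crossing ", name,
             call. = FALSE)
      }
    }
    s <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
    if (abs(f(s)) > 1e-10 * abs(a_peak)) {
      stop("phase_boundaries: root finding for crossing ", name,
           " did not converge", call. = FALSE)
    }
    s
  }
  s <- c(refine(u1, a_peak / 2, "s1"), refine(u2, a_peak / 2, "s2"),
         refine(u3, a_trough / 2, "s3"), refine(u4, a_trough / 2, "s4"))
  s <- s + t0

  structure(list(s1 = s[1], s2 = s[2], s3 = s[3], s4 = s[4],
                 a_peak = a_peak, a_trough = a_trough,
                 a_halfmax = a_peak / 2, a_halfmin = a_trough / 2,
                 params = params, t0 = t0),
            class = "phase_boundaries")
}

#' @export
print.phase_boundaries <- function(x, ...) {
  cat("Growth-phase boundaries (half-max/half-min of the acceleration curve)\n")
  cat(sprintf("  s1 = %.4f  s2 = %.4f  s3 = %.4f  s4 = %.4f\n",
              x$s1, x$s2, x$s3, x$s4))
  cat(sprintf("  a_peak = %.4g  a_trough = %.4g\n", x$a_peak, x$a_trough))
  cat(sprintf("  windows: acceleration t < %.4f | mid-log [%.4f, %.4f) | ",
              x$s2, x$s2, x$s3))
  cat(sprintf("deceleration [%.4f, %.4f) | stationary t >= %.4f\n",
              x$s3, x$s4, x$s4))
  invisible(x)
}

#' Phase labels used throughout the package
#' @return Character vector of the four phase labels.
#' @export
growth_phases <- function() {
  c("acceleration", "midlog", "deceleration", "stationary")
}

#' Assign times to growth phases
#'
#' Maps times to the four growth phases delimited by [phase_boundaries()].
#' Lag is folded into acceleration, and windows are half-open with ties
#' assigned to the later phase: `t < s2` acceleration, `s2 <= t < s3`
#' mid-log, `s3 <= t < s4` deceleration, `t >= s4` stationary.
#'
#' @param t Numeric vector of times.
#' @param boundaries A `"phase_boundaries"` object.
#' @return Character vector of phase labels (see [growth_phases()]).
#' @export
assign_phase <- function(t, boundaries) {
  stopifnot(inherits(boundaries, "phase_boundaries"))
  if (!is.numeric(t) || anyNA(t)) {
    stop("assign_phase: 't' must be numeric without NA", call. = FALSE)
  }
  out <- character(length(t))
  out[t < boundaries$s2] <- "acceleration"
  out[t >= boundaries$s2 & t < boundaries$s3] <- "midlog"
  out[t >= boundaries$s3 & t < boundaries$s4] <- "deceleration"
  out[t >= boundaries$s4] <- "stationary"
  out
}

# [lo, hi) time window of one phase; acceleration opens at -Inf (lag
# merged in), stationary closes at +Inf.
phase_window <- function(boundaries, phase) {
  phase <- match.arg(phase, growth_phases())
  switch(phase,
         acceleration = c(-Inf, boundaries$s2),
         midlog = c(boundaries$s2, boundaries$s3),
         deceleration = c(boundaries$s3, boundaries$s4),
         stationary = c(boundaries$s4, Inf))
}
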