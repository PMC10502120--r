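# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Step-up FDR adjustment computed from the definition:
# q_i = min over sorted positions j with p_(j) >= p_i of m * p_(j) / j,
# capped at 1.  Quadratic, but independent of stats::p.adjust.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min((m / (i:m)) * ps[i:m]))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Second derivative of the closed-form logistic solution by central
# finite differences with one Richardson step (no analytic acceleration
# formula involved); the large-ish step plus extrapolation keeps both
# truncation and roundoff error well below 1e-8 relative.
fd_acceleration <- function(params, t, h = 0.02) {
  x <- function(tt) logistic_solution(params, tt)
  D <- function(hh) (x(t + hh) - 2 * x(t) + x(t - hh)) / hh^2
  R1 <- (4 * D(h / 2) - D(h)) / 3
  R2 <- (4 * D(h / 4) - D(h / 2)) / 3
  (16 * R2 - R1) / 15
}

# Brute-force phase boundaries: dense sign scan of the finite-difference
# acceleration against its half-max / half-min levels, refined by plain
# bisection.  Works on the closed form only.
brute_force_boundaries <- function(params, grid_n = 4000) {
  # span the curve from u = 1e-4 to u = 1 - 1e-6 in abundance fraction
  t_lo <- log(1e-4 * (params$K - params$x0) /
                (params$x0 * (1 - 1e-4))) / params$r
  t_hi <- log((1 - 1e-6) * (params$K - params$x0) /
                (params$x0 * 1e-6)) / params$r
  ts <- seq(t_lo, t_hi, length.out = grid_n)
  acc <- fd_acceleration(params, ts)
  # parabolic refinement of the grid extrema: the raw grid max/min
  # undershoots the true peak level by O(grid step^2), which would bias
  # the half-max crossing times
  refine_extreme <- function(i) {
    y <- acc[(i - 1):(i + 1)]
    y[2] + (y[3] - y[1])^2 / (8 * (2 * y[2] - y[1] - y[3]))
  }
  a_peak <- refine_extreme(which.max(acc))
  a_trough <- refine_extreme(which.min(acc))
  bisect <- function(lo, hi, level) {
    f <- function(t) fd_acceleration(params, t) - level
    flo <- f(lo)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (sign(fm) == sign(flo)) {
        lo <- mid
        flo <- fm
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }
  crossings <- function(level) {
    d <- acc - level
    idx <- which(d[-1] * d[-length(d)] < 0)
    vapply(idx, function(i) bisect(ts[i], ts[i + 1], level), numeric(1))
  }
  up <- crossings(a_peak / 2)
  dn <- crossings(a_trough / 2)
  c(s1 = up[1], s2 = up[2], s3 = dn[1], s4 = dn[2])
}

# Random valid growth parameterizations with all four crossings on the
# curve (x0 below the first crossing abundance fraction ~0.0583 K keeps
# s1 > 0; larger x0 up to K/2 is exercised separately).
random_growth_params <- function(n) {
  lapply(seq_len(n), function(i) {
    K <- 10^stats::runif(1, 1, 3)
    growth_params(r = stats::runif(1, 0.5, 3), K = K,
                  x0 = K * stats::runif(1, 0.002, 0.04))
  })
}

recovery_rate <- function(donor, calls) {
  m <- merge(calls, donor$truth[, c("taxon", "true_phase")],
             by = "taxon")
  nonmid <- m$true_phase != "midlog"
  mean(m$phase[nonmid] == m$true_phase[nonmid])
}
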