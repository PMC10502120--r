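#' Configuration for stochastic logistic growth simulations
#'
#' Collects the settings of one ensemble run of the stochastic logistic
#' growth equation (sLGE) \eqn{dx/dt = r x (1 - x/K) + \sigma x \omega(t)},
#' integrated by the Euler-Maruyama scheme.  Noise can be placed on the
#' abundance (the written SDE, `noise_target = "abundance"`) or on the
#' carrying capacity (`"carrying_capacity"`, a fresh white-noise
#' perturbation of `K` at each step).  An optional harvest (dilution)
#' term `- H x` models proportional removal; its deterministic stable
#' point is `K (1 - H/r)` (see [equilibrium_with_harvest()]).
#'
#' @param params A [growth_params()] object.
#' @param sigma Noise magnitude, `>= 0`.  Default 0.1.
#' @param noise_target `"abundance"` or `"carrying_capacity"`.
#' @param harvest Harvest rate `H >= 0` per unit time; 0 disables.
#' @param t0,t_final Time span of the simulation (defaults 1 and 100).
#' @param n_steps Integration steps per unit time (default 100, i.e.
#'   `dt = 0.01`).
#' @param n_iter Ensemble size (default 100).
#' @param seed Integer seed; the ensemble is fully reproducible, and
#'   iteration `i` consumes its own substream so changing `n_iter` does
#'   not reshuffle earlier paths.
#' @return An object of class `"slge_config"`.
#' @export
slge_config <- function(params, sigma = 0.1,
                        noise_target = c("abundance", "carrying_capacity"),
                        harvest = 0, t0 = 1, t_final = 100,
                        n_steps = 100, n_iter = 100, seed = 42L) {
  params <- as_growth_params(params)
  noise_target <- match.arg(noise_target)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("slge_config: 'sigma' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(harvest) || length(harvest) != 1L || harvest < 0) {
    stop("slge_config: 'harvest' must be a single number >= 0", call. = FALSE)
  }
  stopifnot(t0 < t_final, n_steps >= 1, n_iter >= 1)
  structure(list(params = params, sigma = sigma, noise_target = noise_target,
                 harvest = harvest, t0 = t0, t_final = t_final,
                 n_steps = as.integer(n_steps), n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "slge_config")
}

# Per-iteration noise matrix: row i is drawn under its own seed derived
# from the ensemble seed, so path i is invariant to n_iter.
slge_noise_matrix <- function(seed, n_iter, n_incr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  Z <- matrix(0, n_iter, n_incr)
  for (i in seq_len(n_iter)) {
    set.seed(path_seeds[i])
    Z[i, ] <- stats::rnorm(n_incr)
  }
  Z
}

slge_grid <- function(config) {
  dt <- 1 / config$n_steps
  seq(config$t0, config$t_final, by = dt)
}

#' Simulate a stochastic logistic growth ensemble
#'
#' Integrates the sLGE by Euler-Maruyama:
#' \deqn{x_{j+1} = x_j + [r x_j (1 - x_j/K) - H x_j]\,dt
#'       + \sigma x_j \sqrt{dt}\, Z_j,}
#' with `Z_j` standard normal, independently for each of `n_iter`
#' iterations on a shared time grid.  Paths are clamped at a floor of
#' `1e-12` (absorbing at effective zero).  With
#' `noise_target = "carrying_capacity"` the update is instead the
#' deterministic logistic step evaluated against a per-step perturbed
#' capacity \eqn{k_j = K + \sigma K \sqrt{dt} Z_j} (floored at
#' `1e-6 * K`), which preserves the sigmoidal shape while letting the
#' niche size fluctuate.
#'
#' The deterministic step must resolve the dynamics: configurations with
#' `r * dt > 0.5` are refused.
#'
#' @param config An [slge_config()] object.
#' @return An object of class `"slge_ensemble"`: list with `times` (grid
#'   of length `m`), `abundances` (`n_iter x m` matrix), `deltas`
#'   (`n_iter x (m-1)` forward differences, the simulation-side growth
#'   rate proxy), and `config`.
#' @examples
#' cfg <- slge_config(growth_params(1.2, 100, 1), sigma = 0.1,
#'                    n_iter = 5, seed = 1)
#' ens <- simulate_slge(cfg)
#' dim(ens$abundances)
#' @export
simulate_slge <- function(config) {
  stopifnot(inherits(config, "slge_config"))
  p <- config$params
  dt <- 1 / config$n_steps
  if (p$r * dt > 0.5) {
    stop("simulate_slge: r * dt = ", signif(p$r * dt, 3),
         " > 0.5 - the deterministic step would overshoot; increase ",
         "n_steps", call. = FALSE)
  }
  times <- slge_grid(config)
  m <- length(times)
  n <- config$n_iter
  Z <- slge_noise_matrix(config$seed, n, m - 1L)
  x <- matrix(0, n, m)
  x[, 1] <- p$x0
  sq <- sqrt(dt)
  stochastic_k <- config$noise_target == "carrying_capacity"
  for (j in seq_len(m - 1L)) {
    xj <- x[, j]
    if (stochastic_k) {
      kj <- pmax(p$K + config$sigma * p$K * sq * Z[, j], 1e-6 * p$K)
      drift <- p$r * xj * (1 - xj / kj) - config$harvest * xj
      xnew <- xj + drift * dt
    } else {
      drift <- p$r * xj * (1 - xj / p$K) - config$harvest * xj
      xnew <- xj + drift * dt + config$sigma * xj * sq * Z[, j]
    }
    x[, j + 1L] <- pmax(xnew, 1e-12)
  }
  structure(list(times = times, abundances = x,
                 deltas = x[, -1L, drop = FALSE] - x[, -m, drop = FALSE],
                 config = config),
            class = "slge_ensemble")
}

#' Simulate the stochastic-carrying-capacity variant
#'
#' Convenience wrapper around [simulate_slge()] with
#' `noise_target = "carrying_capacity"`: white noise perturbs the niche
#' size `K` at every step while the abundance update stays deterministic
#' logistic.  At `sigma = 0` both variants reduce exactly to the
#' deterministic Euler path.
#'
#' @inheritParams simulate_slge
#' @return An `"slge_ensemble"` (see [simulate_slge()]).
#' @export
simulate_slge_stochastic_k <- function(config) {
  stopifnot(inherits(config, "slge_config"))
  config$noise_target <- "carrying_capacity"
  simulate_slge(config)
}

#' @export
print.slge_ensemble <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("sLGE ensemble: %d iterations, t in [%g, %g] ",
                     "(dt = %g), sigma = %g on %s%s\n"),
              cfg$n_iter, cfg$t0, cfg$t_final, 1 / cfg$n_steps, cfg$sigma,
              cfg$noise_target,
              if (cfg$harvest > 0) sprintf(", harvest = %g", cfg$harvest)
              else ""))
  cat(sprintf("  r = %g, K = %g, x0 = %g; final abundance %.3g (ensemble mean)\n",
              cfg$params$r, cfg$params$K, cfg$params$x0,
              mean(x$abundances[, ncol(x$abundances)])))
  invisible(x)
}

#' @export
plot.slge_ensemble <- function(x, max_paths = 30, col = "#00000030", ...) {
  n <- min(nrow(x$abundances), max_paths)
  graphics::matplot(x$times, t(x$abundances[seq_len(n), , drop = FALSE]),
                    type = "l", lty = 1, col = col,
                    xlab = "time", ylab = "abundance", ...)
  graphics::lines(x$times,
                  logistic_solution(x$config$params, x$times - x$config$t0),
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate method for growth parameters
#'
#' `simulate()` on a [growth_params()] object runs an sLGE ensemble with
#' the given noise settings; equivalent to building an [slge_config()]
#' and calling [simulate_slge()].
#'
#' @param object A [growth_params()] object.
#' @param nsim Ensemble size.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [slge_config()].
#' @return An `"slge_ensemble"`.
#' @export
simulate.growth_params <- function(object, nsim = 100, seed = 42L, ...) {
  simulate_slge(slge_config(object, n_iter = nsim, seed = seed, ...))
}

#' Stable population size under a harvest term
#'
#' With proportional removal at rate `H`, the logistic equation
#' \eqn{dx/dt = r x (1 - x/K) - H x} has equilibria 0 and
#' \eqn{x^* = K (1 - H/r)}; the latter is the asymptotically stable one
#' whenever `H < r`.  For `H >= r` the only non-negative stable point is
#' extinction, and 0 is returned.
#'
#' @param params A [growth_params()] object.
#' @param H Harvest (dilution) rate, `>= 0`.
#' @return The stable equilibrium abundance.
#' @examples
#' equilibrium_with_harvest(growth_params(1.2, 100, 1), H = 0.6)  # 50
#' @export
equilibrium_with_harvest <- function(params, H) {
  params <- as_growth_params(params)
  if (!is.numeric(H) || length(H) != 1L || H < 0) {
    stop("equilibrium_with_harvest: 'H' must be a single number >= 0",
         call. = FALSE)
  }
  if (H >= params$r) 0 else params$K * (1 - H / params$r)
}

#' Per-iteration delta-abundance correlation within a phase window
#'
#' For each iteration of an ensemble independently, computes the Pearson
#' correlation between the abundance `x(t_j)` and its forward difference
#' `x(t_{j+1}) - x(t_j)` over grid points falling inside the time window
#' of one growth phase.  This is the simulation-side analog of the
#' delta-vs-abundance statistics computed on stool time series:
#' positive in the acceleration window, negative in the deceleration
#' window, and near zero in mid-log for moderate noise.
#'
#' Iterations whose window holds fewer than 3 usable points, or with zero
#' variance, yield `NA` rather than an error.
#'
#' @param ensemble An `"slge_ensemble"` from [simulate_slge()].
#' @param boundaries A `"phase_boundaries"` object on the same absolute
#'   time axis as the ensemble (pass `t0 = config$t0` when constructing
#'   it).
#' @param phase One of [growth_phases()].
#' @param thin Keep every `thin`-th grid point inside the window before
#'   correlating (default 1 = all points).
#' @return Numeric vector of per-iteration correlations (length
#'   `n_iter`), possibly containing `NA`.
#' @export
phase_window_correlation <- function(ensemble, boundaries, phase, thin = 1L) {
  stopifnot(inherits(ensemble, "slge_ensemble"),
            inherits(boundaries, "phase_boundaries"))
  phase <- match.arg(phase, growth_phases())
  w <- phase_window(boundaries, phase)
  m <- length(ensemble$times)
  # deltas pair grid point j with j+1; keep pairs whose left point is in
  # the window
  idx <- which(ensemble$times >= w[1] & ensemble$times < w[2])
  idx <- idx[idx < m]
  if (thin > 1L) idx <- idx[seq(1L, length(idx), by = as.integer(thin))]
  apply_cor <- function(i) {
    xs <- ensemble$abundances[i, idx]
    ds <- ensemble$deltas[i, idx]
    if (length(idx) < 3L || stats::sd(xs) == 0 || stats::sd(ds) == 0) {
      return(NA_real_)
    }
    stats::cor(xs, ds)
  }
  vapply(seq_len(nrow(ensemble$abundances)), apply_cor, numeric(1))
}
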