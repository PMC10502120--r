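#' Deterministic logistic growth parameters
#'
#' Bundles the three parameters of the logistic growth equation
#' \eqn{dx/dt = r x (1 - x/K)}: the maximal growth rate `r` (per unit
#' time), the carrying capacity `K` (abundance units), and the initial
#' abundance `x0`.  The same object parameterizes the closed-form
#' analytics ([logistic_solution()], [phase_boundaries()]) and the
#' stochastic simulator ([simulate_slge()]).
#'
#' Canonical growth curves require `0 < x0 < K`; the closed-form solution
#' also supports `x0 > K` (monotone decay toward `K`), but the
#' phase-boundary machinery refuses curves starting at or past `K/2`
#' (see [phase_boundaries()]).
#'
#' @param r Maximal growth rate, `> 0`.
#' @param K Carrying capacity, `> 0`.
#' @param x0 Initial abundance, `> 0`.
#' @return An object of class `"growth_params"`.
#' @examples
#' gp <- growth_params(r = 1.2, K = 100, x0 = 1)
#' logistic_solution(gp, c(0, 2, 4, 8))
#' @export
growth_params <- function(r, K, x0 = 1) {
  for (nm in c("r", "K", "x0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("growth_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(list(r = r, K = K, x0 = x0), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Logistic growth parameters: r = %g, K = %g, x0 = %g\n",
              x$r, x$K, x$x0))
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  if (is.list(x) && all(c("r", "K", "x0") %in% names(x))) {
    return(growth_params(x$r, x$K, x$x0))
  }
  stop("expected a 'growth_params' object", call. = FALSE)
}
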