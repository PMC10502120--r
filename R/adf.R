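# Dickey-Fuller tau distribution quantiles for the constant+trend
# regression (Banerjee et al. 1993, Table 4.2; the standard table for
# this test).  Rows: sample sizes 25, 50, 100, 250, 500, Inf; columns:
# cumulative probabilities.
.adf_tau_ct <- list(
  n = c(25, 50, 100, 250, 500, 1e5),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = cbind(
    c(-4.38, -4.15, -4.04, -3.99, -3.98, -3.96),
    c(-3.95, -3.80, -3.73, -3.69, -3.68, -3.66),
    c(-3.60, -3.50, -3.45, -3.43, -3.42, -3.41),
    c(-3.24, -3.18, -3.15, -3.13, -3.13, -3.12),
    c(-1.14, -1.19, -1.22, -1.23, -1.24, -1.25),
    c(-0.80, -0.87, -0.90, -0.92, -0.93, -0.94),
    c(-0.50, -0.58, -0.62, -0.64, -0.65, -0.66),
    c(-0.15, -0.24, -0.28, -0.31, -0.32, -0.33))
)

adf_fit <- function(y, k) {
  n <- length(y)
  dy <- diff(y)
  idx <- (k + 1L):(n - 1L)           # rows of the ADF regression
  X <- cbind(1, idx, y[idx])
  if (k > 0L) {
    lagmat <- sapply(seq_len(k), function(j) dy[idx - j])
    X <- cbind(X, lagmat)
  }
  resp <- dy[idx]
  fit <- stats::lm.fit(X, resp)
  rss <- sum(fit$residuals^2)
  nobs <- length(resp)
  npar <- ncol(X)
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * rss / (nobs - npar))
  list(stat = fit$coefficients[3] / se[3],
       aic = nobs * log(rss / nobs) + 2 * npar,
       nobs = nobs)
}

#' Augmented Dickey-Fuller stationarity screen
#'
#' Tests the unit-root null against the stationary alternative with the
#' ADF regression including constant and linear trend:
#' \deqn{\Delta y_t = \alpha + \beta t + \gamma y_{t-1}
#'       + \sum_{j=1}^{k} \delta_j \Delta y_{t-j} + \epsilon_t,}
#' referring the t-statistic of \eqn{\gamma} to the Dickey-Fuller tau
#' distribution (interpolated from the standard table for the
#' constant+trend case; p-values are clipped to `[0.01, 0.99]`).
#' A *significant* p-value rejects the unit root, i.e. indicates
#' stationarity; the returned flag applies the `p < threshold`
#' stationarity rule (default 0.1).
#'
#' The lag order is selected by AIC over `0..kmax` with
#' `kmax = trunc((n - 1)^(1/3))` (models compared on a common sample),
#' or fixed by passing an integer `lags`.
#'
#' @param values Ordered numeric series, at least 20 points, no missing
#'   values.
#' @param threshold Stationarity significance level (default 0.1).
#' @param lags `"aic"` (default) or a fixed non-negative integer.
#' @return List with `p` (interpolated p-value), `stationary` (logical
#'   flag `p < threshold`), `statistic`, `lags`, and `status` (`"ok"`,
#'   or `"too_short"` / `"constant"` with `NA` results).
#' @export
adf_stationarity <- function(values, threshold = 0.1, lags = "aic") {
  na_result <- function(status) {
    list(p = NA_real_, stationary = NA, statistic = NA_real_,
         lags = NA_integer_, status = status)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("adf_stationarity: complete numeric series required",
         call. = FALSE)
  }
  n <- length(values)
  if (n < 20L) return(na_result("too_short"))
  if (stats::sd(values) == 0) return(na_result("constant"))

  kmax <- max(0L, as.integer(trunc((n - 1)^(1/3))))
  if (identical(lags, "aic")) {
    # compare AIC on the common sample implied by the largest lag order
    aics <- vapply(0:kmax, function(k) {
      y <- values[(kmax - k + 1L):n]
      adf_fit(y, k)$aic
    }, numeric(1))
    k <- which.min(aics) - 1L
  } else {
    k <- as.integer(lags)
    stopifnot(k >= 0L, k <= n - 5L)
  }
  res <- adf_fit(values, k)

  tab <- .adf_tau_ct
  qn <- vapply(seq_along(tab$p), function(j) {
    stats::approx(tab$n, tab$q[, j], xout = res$nobs, rule = 2)$y
  }, numeric(1))
  p <- stats::approx(qn, tab$p, xout = res$stat, rule = 2)$y
  list(p = p, stationary = p < threshold, statistic = unname(res$stat),
       lags = k, status = "ok")
}
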