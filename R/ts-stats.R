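#' Centered log-ratio transform of count compositions
#'
#' Transforms raw read counts to CLR values per sample:
#' \eqn{\mathrm{clr}_i = \ln(c_i + p) - \frac{1}{D}\sum_j \ln(c_j + p)},
#' where the mean runs over all `D` taxa in the sample and `p` is a
#' pseudocount handling zeros.  Each sample's CLR values sum to zero, and
#' the transform is invariant to multiplying a sample's counts (plus
#' pseudocounts) by a positive constant.
#'
#' All taxa present in the table enter the geometric mean; filtering to
#' abundant taxa is done after transformation, not before.
#'
#' @param counts Numeric matrix or data frame, taxa in rows and samples
#'   in columns, non-negative counts.
#' @param pseudocount Added to every count before taking logs
#'   (default 0.5).
#' @return Numeric matrix of CLR values with the same dimnames.
#' @examples
#' clr_transform(cbind(s1 = c(2, 8)))  # -log(2)/+log(2) at pseudocount 0
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("clr_transform: counts must be non-negative and complete",
         call. = FALSE)
  }
  if (nrow(counts) < 2L) {
    stop("clr_transform: need at least 2 taxa per sample", call. = FALSE)
  }
  zero_samples <- which(colSums(counts) == 0)
  if (length(zero_samples)) {
    nm <- colnames(counts)[zero_samples]
    if (is.null(nm)) nm <- as.character(zero_samples)
    stop("clr_transform: sample(s) with all-zero counts: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  lg <- log(counts + pseudocount)
  sweep(lg, 2L, colMeans(lg), "-")
}

#' Day-gated abundance deltas
#'
#' For each pair of consecutive samples of one taxon whose day gap is
#' strictly below `max_gap`, emits the pair (abundance at the earlier
#' day, change to the next day).  Pairs violating the gate are dropped,
#' never interpolated; with daily-to-every-other-day stool sampling the
#' default gate (`< 3` days) keeps gaps of 1 and 2 days.
#'
#' @param series A [taxon_series()] (or any list with `days` and `clr`).
#' @param max_gap Strict upper bound on the day gap (default 3).
#' @return Data frame with columns `abundance` and `delta` (possibly 0
#'   rows).
#' @export
compute_deltas <- function(series, max_gap = 3) {
  days <- series$days
  clr <- series$clr
  stopifnot(length(days) == length(clr))
  if (length(days) < 2L) {
    return(data.frame(abundance = numeric(0), delta = numeric(0)))
  }
  gap <- diff(days)
  keep <- which(gap < max_gap)
  data.frame(abundance = clr[keep], delta = clr[keep + 1L] - clr[keep])
}

# Internal constructor for regression summaries; NA fields plus a status
# mark ineligible / degenerate inputs instead of raising.
regression_result <- function(slope = NA_real_, intercept = NA_real_,
                              pearson_r = NA_real_, p = NA_real_,
                              q = NA_real_, n = 0L, status = "ok") {
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = pearson_r, p = p, q = q, n = as.integer(n),
                 status = status),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Regression result: <%s> (n = %d)\n", x$status, x$n))
  } else {
    cat(sprintf(
      "Regression result: slope %.4g, r %.3f, p %.3g%s, n %d\n",
      x$slope, x$pearson_r, x$p,
      if (is.na(x$q)) "" else sprintf(", q %.3g", x$q), x$n))
  }
  invisible(x)
}

ols_with_cor <- function(x, y) {
  fit <- stats::lm(y ~ x)
  # for simple OLS the slope t-test and the Pearson correlation test
  # coincide; cor.test also stays quiet on exact fits
  ct <- stats::cor.test(x, y)
  regression_result(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    pearson_r = unname(ct$estimate),
                    p = ct$p.value,
                    n = length(x))
}

#' Delta-vs-abundance statistics (regression-to-the-mean diagnostic)
#'
#' Pearson correlation and OLS fit of the abundance change (delta) on the
#' abundance at the earlier time point.  For populations fluctuating
#' around a fixed carrying capacity this is systematically negative -
#' the regression-to-the-mean signature of sampling a stationary
#' distribution - so a strongly negative value is evidence *against*
#' reading day-to-day deltas as growth.
#'
#' @param pairs Data frame from [compute_deltas()] (columns `abundance`,
#'   `delta`).
#' @return A `regression_result`; status `"too_few_points"` below 3
#'   pairs, `"zero_variance"` for constant abundances.
#' @export
delta_abundance_stats <- function(pairs) {
  if (nrow(pairs) < 3L) {
    return(regression_result(n = nrow(pairs), status = "too_few_points"))
  }
  if (stats::sd(pairs$abundance) == 0) {
    return(regression_result(n = nrow(pairs), status = "zero_variance"))
  }
  ols_with_cor(pairs$abundance, pairs$delta)
}

#' Per-taxon regression of CLR abundance on log2(PTR)
#'
#' Ordinary least squares of the CLR-normalized abundance (response)
#' against the log2 peak-to-trough ratio, over days where both are
#' available.  Taxa need strictly more than `min_points` matched time
#' points to be eligible; ineligible taxa get status `"ineligible"` and
#' are carried through batch steps rather than raising.  The Pearson
#' correlation is reported alongside; the slope *sign* (which is what
#' the phase classifier consumes) is orientation-free.
#'
#' @param series A [taxon_series()].
#' @param min_points Eligibility cutoff: require `n > min_points`
#'   matched points (default 5).
#' @return A `regression_result`.
#' @export
ptr_abundance_regression <- function(series, min_points = 5L) {
  ok <- !is.na(series$clr) & !is.na(series$log2ptr)
  n <- sum(ok)
  if (n <= min_points) {
    return(regression_result(n = n, status = "ineligible"))
  }
  x <- series$log2ptr[ok]
  y <- series$clr[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(regression_result(n = n, status = "zero_variance"))
  }
  ols_with_cor(x, y)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating, order-preserving
#' wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (`NA` allowed;
#'   propagated).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("bh_adjust: numeric input required",
                                 call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Combine p-values with Fisher's method
#'
#' Computes \eqn{X = -2 \sum_i \ln p_i} and refers it to the chi-square
#' distribution with `2k` degrees of freedom, returning the upper-tail
#' probability.  Used to combine per-donor regression p-values into one
#' cohort-level p-value.
#'
#' @param pvalues Numeric vector of independent p-values in `(0, 1]`.
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(0.0318, 0.125, 0.155, 0.031))  # ~0.005
#' @export
fisher_combine <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) < 1L || anyNA(pvalues)) {
    stop("fisher_combine: need a complete numeric vector", call. = FALSE)
  }
  if (any(pvalues <= 0)) {
    stop("fisher_combine: p = 0 gives an infinite statistic", call. = FALSE)
  }
  if (any(pvalues > 1)) {
    stop("fisher_combine: p-values must lie in (0, 1]", call. = FALSE)
  }
  X <- -2 * sum(log(pvalues))
  stats::pchisq(X, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Donor-level regression of mean abundance on mean replication rate
#'
#' Across the eligible taxa of one donor, regresses the per-taxon mean
#' CLR abundance (response) on the per-taxon mean log2(PTR).  The
#' per-donor p-values from this regression are the inputs to
#' [fisher_combine()].
#'
#' @param series_list List of [taxon_series()] for one donor.
#' @param min_points Per-taxon eligibility cutoff (see
#'   [ptr_abundance_regression()]).
#' @return A `regression_result`; status `"too_few_taxa"` below 3
#'   eligible taxa.
#' @export
donor_mean_regression <- function(series_list, min_points = 5L) {
  keep <- vapply(series_list, function(s) {
    sum(!is.na(s$clr) & !is.na(s$log2ptr)) > min_points
  }, logical(1))
  series_list <- series_list[keep]
  if (length(series_list) < 3L) {
    return(regression_result(n = length(series_list),
                             status = "too_few_taxa"))
  }
  mean_ptr <- vapply(series_list,
                     function(s) mean(s$log2ptr, na.rm = TRUE), numeric(1))
  mean_clr <- vapply(series_list,
                     function(s) mean(s$clr, na.rm = TRUE), numeric(1))
  if (stats::sd(mean_ptr) == 0) {
    return(regression_result(n = length(series_list),
                             status = "zero_variance"))
  }
  ols_with_cor(mean_ptr, mean_clr)
}

#' Taxonomy-adjusted association between replication rate and abundance
#'
#' Pools (CLR, log2PTR) observations across taxa and fits
#' `log2ptr ~ clr + group`, where `group` is a taxonomic categorization
#' (class- or species-level), returning the `clr` coefficient and its
#' p-value.  Group indicators absorb between-taxon baseline differences
#' so the slope reflects the within-group association (guards against
#' Simpson's-paradox reversals in the pooled fit).
#'
#' Groups with fewer than `min_per_group` rows are dropped.  With a
#' single (remaining) group the model is degenerate; a simple regression
#' is fitted instead, with a warning.
#'
#' @param data Data frame with numeric columns `clr`, `log2ptr` and a
#'   grouping column.
#' @param grouping Name of the grouping column (default `"group"`).
#' @param min_per_group Minimum rows per included group (default 3).
#' @return List with `slope` (the `clr` coefficient), `p`, `n`,
#'   `n_groups`, and the fitted `lm` object as `fit`.
#' @export
covariate_adjusted_regression <- function(data, grouping = "group",
                                          min_per_group = 3L) {
  stopifnot(is.data.frame(data),
            all(c("clr", "log2ptr", grouping) %in% names(data)))
  g <- factor(data[[grouping]])
  tab <- table(g)
  keep <- g %in% names(tab)[tab >= min_per_group]
  data <- data[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  if (nrow(data) < 3L) {
    stop("covariate_adjusted_regression: fewer than 3 usable rows",
         call. = FALSE)
  }
  if (nlevels(g) < 2L) {
    warning("covariate_adjusted_regression: single taxon group - ",
            "falling back to simple regression")
    fit <- stats::lm(log2ptr ~ clr, data = data)
  } else {
    data$.group <- g
    fit <- stats::lm(log2ptr ~ clr + .group, data = data)
  }
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)["clr"]),
       p = sm["clr", 4],
       n = nrow(data), n_groups = nlevels(g), fit = fit)
}
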