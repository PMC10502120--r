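#' Configuration of the growth-phase classifier
#'
#' @param stationary_threshold Mean log2(PTR) below which a taxon is
#'   called stationary.  The default 0.358 is the experimentally
#'   determined mean log2(PTR) of in vitro stationary-phase *E. coli*;
#'   it is deliberately a configuration value, not a constant baked into
#'   the rules.
#' @param alpha FDR significance level for the slope test (default
#'   0.05).
#' @param min_points Eligibility: a taxon needs strictly more than this
#'   many matched (CLR, log2PTR) time points (default 5).
#' @return An object of class `"classifier_config"`.
#' @export
classifier_config <- function(stationary_threshold = 0.358, alpha = 0.05,
                              min_points = 5L) {
  stopifnot(is.numeric(stationary_threshold),
            length(stationary_threshold) == 1L, stationary_threshold >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            min_points >= 0)
  structure(list(stationary_threshold = stationary_threshold,
                 alpha = alpha, min_points = as.integer(min_points)),
            class = "classifier_config")
}

phase_call_labels <- function() {
  c("stationary", "acceleration", "deceleration",
    "midlog_or_indeterminate", "ineligible")
}

phase_call <- function(taxon, donor, phase, mean_log2ptr, slope, p, q, n,
                       flag = "") {
  data.frame(taxon = taxon, donor = donor, phase = phase,
             mean_log2ptr = mean_log2ptr, slope = slope, p = p, q = q,
             n = as.integer(n), flag = flag, stringsAsFactors = FALSE)
}

#' Classify one taxon's growth phase from its summary statistics
#'
#' Applies the rule-based decision in fixed order: (1) a mean log2(PTR)
#' below the stationary threshold is called `stationary` (regardless of
#' the slope - the empirical threshold takes precedence; a significant
#' slope in this regime is flagged in the output); (2) an FDR-adjusted
#' p below `alpha` with positive slope is `acceleration`; (3) with
#' negative slope, `deceleration`; (4) otherwise
#' `midlog_or_indeterminate` - deliberately not "mid-log", since a null
#' slope can also be an underpowered acceleration/deceleration signal.
#'
#' @param stats A `regression_result` from [ptr_abundance_regression()]
#'   with the batch FDR step already applied (`q` filled); an error is
#'   raised otherwise.
#' @param mean_log2ptr The taxon's missing-aware mean log2(PTR).
#' @param config A [classifier_config()].
#' @param taxon,donor Identifiers carried into the output.
#' @return One-row data frame (a phase call) with columns `taxon`,
#'   `donor`, `phase`, `mean_log2ptr`, `slope`, `p`, `q`, `n`, `flag`.
#' @export
classify_taxon <- function(stats, mean_log2ptr, config = classifier_config(),
                           taxon = NA_character_, donor = NA_character_) {
  stopifnot(inherits(config, "classifier_config"))
  if (stats$status %in% c("ineligible", "too_few_points")) {
    return(phase_call(taxon, donor, "ineligible", mean_log2ptr,
                      NA_real_, NA_real_, NA_real_, stats$n))
  }
  if (stats$status == "ok" && is.na(stats$q)) {
    stop("classify_taxon: 'q' is missing - apply the batch FDR ",
         "correction (bh_adjust across the donor's taxa) before ",
         "classifying", call. = FALSE)
  }
  slope <- stats$slope
  q <- stats$q
  significant <- stats$status == "ok" && !is.na(q) && q < config$alpha
  if (!is.na(mean_log2ptr) && mean_log2ptr < config$stationary_threshold) {
    flag <- if (significant) "significant_slope_below_threshold" else ""
    return(phase_call(taxon, donor, "stationary", mean_log2ptr, slope,
                      stats$p, q, stats$n, flag))
  }
  phase <- if (significant && slope > 0) {
    "acceleration"
  } else if (significant && slope < 0) {
    "deceleration"
  } else {
    "midlog_or_indeterminate"
  }
  phase_call(taxon, donor, phase, mean_log2ptr, slope, stats$p, q, stats$n)
}

#' Classify all taxa of one donor
#'
#' Runs [ptr_abundance_regression()] for every taxon, applies a
#' Benjamini-Hochberg correction across the donor's eligible taxa (the
#' FDR family is per donor), then applies [classify_taxon()] to each.
#' Ineligible taxa (too few matched points) are carried through with
#' phase `"ineligible"` and do not enter the FDR family.  Output order
#' equals input order.
#'
#' @param series_list List of [taxon_series()] objects for one donor.
#' @param config A [classifier_config()].
#' @return Data frame of phase calls, one row per input taxon.
#' @export
classify_donor <- function(series_list, config = classifier_config()) {
  stopifnot(length(series_list) >= 1L)
  stats_list <- lapply(series_list, ptr_abundance_regression,
                       min_points = config$min_points)
  eligible <- vapply(stats_list, function(s) s$status != "ineligible",
                     logical(1))
  qs <- bh_adjust(vapply(stats_list, `[[`, numeric(1), "p")[eligible])
  stats_list[eligible] <- Map(function(s, q) { s$q <- q; s },
                              stats_list[eligible],
                              as.list(qs))
  calls <- Map(function(s, st) {
    classify_taxon(st, mean_log2ptr(s), config,
                   taxon = s$taxon, donor = s$donor)
  }, series_list, stats_list)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
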