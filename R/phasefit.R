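#' Fit growth-phase calls to one donor's metagenomic time series
#'
#' The central fitting routine: takes a taxon-by-sample read count
#' table, a matching log2 peak-to-trough ratio table and sample
#' metadata, restricts them to one donor, CLR-transforms the counts
#' (all taxa enter the geometric mean), builds per-taxon longitudinal
#' series, and estimates each abundant taxon's in situ growth phase
#' from its mean log2(PTR) and the FDR-corrected slope of its CLR
#' abundance on log2(PTR) (see [classify_donor()] for the decision
#' rules).  Regression-to-the-mean diagnostics (day-gated
#' delta-vs-abundance statistics) and the donor-level mean-vs-mean
#' regression are computed alongside.
#'
#' @param abundance Counts matrix (taxa x samples) or path to a TSV
#'   (see [read_abundance_table()]).
#' @param ptr log2(PTR) matrix or path to a CSV (see
#'   [read_ptr_table()]).
#' @param metadata Data frame or path to a TSV with `sample_id`,
#'   `donor_id`, `day`.
#' @param donor Donor identifier; may be omitted when the metadata
#'   holds a single donor.
#' @param config A [classifier_config()].
#' @param pseudocount CLR pseudocount (default 0.5).
#' @param max_gap Strict day-gap gate for delta computation (default 3).
#' @return An object of class `"phasefit"`: list with `calls` (the
#'   phase-call data frame), `series` (list of [taxon_series()]),
#'   `delta_stats` (per-taxon regression-to-the-mean summaries),
#'   `donor_mean` (donor-level mean-vs-mean `regression_result`),
#'   `donor`, `config`, `n_samples`.
#' @examples
#' d <- generate_donor(donor_spec(n_timepoints = 25, seed = 7))
#' fit <- phasefit(d$counts, d$ptr, d$metadata)
#' print(fit)
#' coef(fit)
#' @export
phasefit <- function(abundance, ptr, metadata, donor = NULL,
                     config = classifier_config(), pseudocount = 0.5,
                     max_gap = 3) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(abundance)) {
    abundance <- read_abundance_table(abundance, metadata)
  }
  if (is.character(ptr)) ptr <- read_ptr_table(ptr)
  abundance <- as.matrix(abundance)
  ptr <- as.matrix(ptr)
  donors <- unique(metadata$donor_id)
  if (is.null(donor)) {
    if (length(donors) != 1L) {
      stop("phasefit: metadata holds ", length(donors),
           " donors; pass 'donor'", call. = FALSE)
    }
    donor <- donors
  }
  series <- build_donor_series(abundance, ptr, metadata, donor,
                               pseudocount = pseudocount)
  calls <- classify_donor(series, config = config)
  delta_stats <- do.call(rbind, lapply(series, function(s) {
    st <- delta_abundance_stats(compute_deltas(s, max_gap = max_gap))
    data.frame(taxon = s$taxon, pearson_r = st$pearson_r,
               slope = st$slope, p = st$p, n_pairs = st$n,
               status = st$status, stringsAsFactors = FALSE)
  }))
  structure(list(calls = calls, series = series,
                 delta_stats = delta_stats,
                 donor_mean = donor_mean_regression(
                   series, min_points = config$min_points),
                 donor = donor, config = config,
                 n_samples = length(series[[1L]]$days)),
            class = "phasefit")
}

#' @export
print.phasefit <- function(x, ...) {
  cat(sprintf("Growth-phase fit for donor %s: %d taxa, %d samples\n",
              x$donor, nrow(x$calls), x$n_samples))
  tab <- table(factor(x$calls$phase, levels = phase_call_labels()))
  for (ph in names(tab)) {
    if (tab[[ph]] > 0) cat(sprintf("  %-24s %d\n", ph, tab[[ph]]))
  }
  invisible(x)
}

#' @export
summary.phasefit <- function(object, ...) {
  structure(list(fit = object), class = "summary.phasefit")
}

#' @export
print.summary.phasefit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("\nClassifier: stationary threshold %.3f, alpha %.2f, > %d matched points\n",
              fit$config$stationary_threshold, fit$config$alpha,
              fit$config$min_points))
  dm <- fit$donor_mean
  if (dm$status == "ok") {
    cat(sprintf(
      "Donor-level mean CLR ~ mean log2PTR: slope %.3f, r %.3f, p %.3g (%d taxa)\n",
      dm$slope, dm$pearson_r, dm$p, dm$n))
  }
  rtm <- fit$delta_stats$pearson_r
  if (any(!is.na(rtm))) {
    cat(sprintf(
      "Regression-to-the-mean: delta-vs-abundance r median %.3f (%d/%d taxa negative)\n",
      stats::median(rtm, na.rm = TRUE), sum(rtm < 0, na.rm = TRUE),
      sum(!is.na(rtm))))
  }
  cat("\nPhase calls:\n")
  print(fit$calls[, c("taxon", "phase", "mean_log2ptr", "slope", "q",
                      "n")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Per-taxon log2(PTR)-abundance slopes of a phase fit
#' @param object A `"phasefit"`.
#' @param ... Unused.
#' @return Named numeric vector of regression slopes (eligible taxa).
#' @export
coef.phasefit <- function(object, ...) {
  ok <- object$calls$phase != "ineligible"
  stats::setNames(object$calls$slope[ok], object$calls$taxon[ok])
}

#' Plot a phase fit
#'
#' Scatter of the per-taxon regression slope against the mean
#' log2(PTR), coloured by phase call, with the stationary threshold
#' drawn as a horizontal line.
#'
#' @param x A `"phasefit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phasefit <- function(x, ...) {
  calls <- x$calls[x$calls$phase != "ineligible", , drop = FALSE]
  cols <- c(stationary = "navy", acceleration = "darkorange",
            deceleration = "steelblue",
            midlog_or_indeterminate = "grey50")
  graphics::plot(calls$slope, calls$mean_log2ptr,
                 col = cols[calls$phase], pch = 19,
                 xlab = "log2(PTR) ~ CLR abundance slope",
                 ylab = "mean log2(PTR)", ...)
  graphics::abline(h = x$config$stationary_threshold, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
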