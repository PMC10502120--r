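#' One taxon's longitudinal record within a donor
#'
#' Aligned vectors of collection days, CLR-transformed abundances and
#' log2 peak-to-trough ratios (missing PTR values allowed) for one taxon
#' in one donor's time series.  Summary means are always recomputed from
#' the stored vectors (see [mean_log2ptr()]), never cached.
#'
#' @param taxon,donor Identifiers.
#' @param days Strictly increasing integer collection days.
#' @param clr CLR abundance per day.
#' @param log2ptr log2(PTR) per day; `NA` where the estimator produced
#'   no value.
#' @return An object of class `"taxon_series"`.
#' @export
taxon_series <- function(taxon, donor, days, clr, log2ptr) {
  days <- as.numeric(days)
  if (length(days) != length(clr) || length(days) != length(log2ptr)) {
    stop("taxon_series: days, clr and log2ptr must be aligned",
         call. = FALSE)
  }
  if (anyNA(days) || any(diff(days) <= 0)) {
    stop("taxon_series: days must be strictly increasing", call. = FALSE)
  }
  structure(list(taxon = as.character(taxon), donor = as.character(donor),
                 days = days, clr = as.numeric(clr),
                 log2ptr = as.numeric(log2ptr)),
            class = "taxon_series")
}

#' @export
print.taxon_series <- function(x, ...) {
  cat(sprintf(
    "Taxon series %s (donor %s): %d days, mean CLR %.3f, mean log2PTR %s\n",
    x$taxon, x$donor, length(x$days), mean_clr(x),
    ifelse(all(is.na(x$log2ptr)), "NA",
           sprintf("%.3f", mean_log2ptr(x)))))
  invisible(x)
}

#' Missing-aware summary means of a taxon series
#'
#' @param series A [taxon_series()].
#' @return Arithmetic mean over available time points.
#' @export
mean_log2ptr <- function(series) mean(series$log2ptr, na.rm = TRUE)

#' @rdname mean_log2ptr
#' @export
mean_clr <- function(series) mean(series$clr, na.rm = TRUE)
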