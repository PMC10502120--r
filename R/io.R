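# File dialects: counts/metadata/phase calls are TSV, PTR tables are CSV
# (mirroring the export habits of replication-rate estimators); UTF-8,
# '.' decimal, blanks = missing in PTR tables only.

#' Read a taxon-by-sample abundance (read count) table
#'
#' TSV with the taxon identifier in the first column and one column per
#' sample; cells must be non-negative integers.  Duplicate taxon
#' identifiers are rejected, malformed cells are reported with row and
#' column coordinates, and - when metadata is supplied - every sample
#' column must be listed in it.
#'
#' @param path Path to the TSV file.
#' @param metadata Optional metadata data frame (see
#'   [read_metadata()]) used to validate sample ids.
#' @return Integer matrix, taxa in rows, samples in columns.
#' @export
read_abundance_table <- function(path, metadata = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("read_abundance_table: ", path, ": need a taxon column plus ",
         "at least one sample column", call. = FALSE)
  }
  taxa <- raw[[1L]]
  if (anyDuplicated(taxa)) {
    stop("read_abundance_table: duplicated taxon id(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "read_abundance_table: malformed count '%s' at row %d (taxon %s), column '%s'",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], taxa[bad[1, 1]],
      colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  out <- matrix(as.integer(num), nrow(num),
                dimnames = list(taxa, colnames(cells)))
  if (!is.null(metadata)) {
    unknown <- setdiff(colnames(out), metadata$sample_id)
    if (length(unknown)) {
      stop("read_abundance_table: sample(s) absent from metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Read a taxon-by-sample log2(PTR) table
#'
#' CSV with the taxon identifier in the first column; real-valued cells,
#' blanks preserved as missing (never zero).  Negative log2(PTR) values
#' are allowed - PTR estimates below 1 are a known estimator artifact -
#' but their count is reported as a warning.  Non-numeric non-blank
#' cells are reported with coordinates.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix with `NA` for missing cells.
#' @export
read_ptr_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("read_ptr_table: ", path, ": need a taxon column plus at ",
         "least one sample column", call. = FALSE)
  }
  taxa <- raw[[1L]]
  if (anyDuplicated(taxa)) {
    stop("read_ptr_table: duplicated taxon id(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  blank <- !nzchar(trimws(cells)) | is.na(cells)
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(num) & !blank, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "read_ptr_table: non-numeric cell '%s' at row %d (taxon %s), column '%s'",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], taxa[bad[1, 1]],
      colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  num[blank] <- NA_real_
  neg <- sum(num < 0, na.rm = TRUE)
  if (neg > 0) {
    warning("read_ptr_table: ", neg, " negative log2(PTR) value(s) ",
            "(PTR < 1 estimator artifact) retained")
  }
  matrix(num, nrow(num), dimnames = list(taxa, colnames(cells)))
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `donor_id`, `day` (integer days since
#' the donor's first sample).
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "donor_id", "day")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop("read_metadata: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("read_metadata: duplicated sample id(s)", call. = FALSE)
  }
  md$day <- as.integer(md$day)
  if (anyNA(md$day)) stop("read_metadata: non-integer day values",
                          call. = FALSE)
  md[need]
}

write_counts_table <- function(counts, path) {
  df <- data.frame(taxon = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_ptr_table <- function(ptr, path) {
  df <- data.frame(taxon = rownames(ptr), ptr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Write phase calls plus a per-phase count summary
#'
#' Writes the call table as TSV with the stable column order `taxon`,
#' `donor`, `phase`, `mean_log2ptr`, `slope`, `p`, `q`, `n` (plus
#' `flag`), and a JSON sidecar (`<path>.json`) with per-phase counts.
#'
#' @param calls Data frame of phase calls (see [classify_donor()]).
#' @param path Output TSV path.
#' @return Invisibly, the named vector of per-phase counts.
#' @export
write_phase_calls <- function(calls, path) {
  cols <- c("taxon", "donor", "phase", "mean_log2ptr", "slope", "p",
            "q", "n", "flag")
  if (!"flag" %in% names(calls)) calls$flag <- ""
  missing_cols <- setdiff(cols, names(calls))
  if (length(missing_cols)) {
    stop("write_phase_calls: calls lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- vapply(phase_call_labels(),
                   function(ph) sum(calls$phase == ph), integer(1))
  jsonlite::write_json(as.list(counts), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(counts)
}

#' Read back a phase-call table written by [write_phase_calls()]
#' @param path TSV path.
#' @return Data frame of phase calls.
#' @export
read_phase_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$flag[is.na(df$flag)] <- ""
  df
}

# Restrict counts + PTR matrices to one donor's samples, day-ordered,
# and build a taxon_series per abundance-table taxon.  Sample columns
# present in only one of the two tables fall back to the intersection
# (counts reported via message).
build_donor_series <- function(counts, ptr, metadata, donor,
                               pseudocount = 0.5) {
  md <- metadata[metadata$donor_id == donor, , drop = FALSE]
  if (nrow(md) == 0L) {
    stop("no samples for donor '", donor, "' in metadata", call. = FALSE)
  }
  md <- md[order(md$day), , drop = FALSE]
  samples <- intersect(md$sample_id, colnames(counts))
  if (length(samples) < length(md$sample_id)) {
    message(length(md$sample_id) - length(samples),
            " metadata sample(s) absent from the abundance table")
  }
  md <- md[md$sample_id %in% samples, , drop = FALSE]
  clr <- clr_transform(counts[, md$sample_id, drop = FALSE],
                       pseudocount = pseudocount)
  ptr_samples <- intersect(md$sample_id, colnames(ptr))
  if (length(ptr_samples) < nrow(md)) {
    message(nrow(md) - length(ptr_samples),
            " sample(s) lack PTR columns; treated as missing")
  }
  lapply(rownames(counts), function(tx) {
    lp <- rep(NA_real_, nrow(md))
    if (tx %in% rownames(ptr)) {
      lp[match(ptr_samples, md$sample_id)] <- ptr[tx, ptr_samples]
    }
    taxon_series(tx, donor, md$day, clr[tx, ], lp)
  })
}
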