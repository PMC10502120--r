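#' Specification of one synthetic taxon
#'
#' Describes how one ground-truth taxon is simulated: its logistic
#' growth parameters and sLGE noise, the phase window it is sampled in
#' (a stool sample always reads the taxon at a random time inside its
#' fixed true-phase window), and the affine map from growth to
#' replication rate,
#' \deqn{\log_2 PTR = b_0 + b_1 \, g + \epsilon,\qquad
#'       g = \frac{dx/dt}{rK/4} \in [0, 1],}
#' where `g` is the effective growth rate normalized by its peak and
#' \eqn{\epsilon \sim N(0, \mathrm{ptr\_noise\_sd}^2)}.  Coupling the PTR
#' to the absolute effective growth rate (not the per-capita rate)
#' reproduces the expected phase signatures: rising with abundance in
#' acceleration, falling in deceleration, flat near the mid-log peak,
#' and near the floor in stationary phase.  The rate is evaluated on
#' the deterministic curve at the sampled time - the replication state
#' follows the position along the growth curve, while the stochastic
#' abundance fluctuation is ecological/observational noise that does
#' not feed back into replication (in vitro stationary populations show
#' a null PTR-abundance association, not the rebound coupling the
#' logistic drift would imply).
#'
#' Defaults encode the in vitro *E. coli* anchors: `ptr_intercept`
#' (log2 PTR at zero growth) is 0.30, the deep-stationary floor observed
#' in vitro, and `ptr_slope` is calibrated per taxon so that the
#' *mid-log window mean* equals the printed mid-log anchor 1.25; the
#' stationary-window mean then lands just above the floor and below the
#' 0.358 stationary threshold, as observed for classified-stationary
#' taxa in real donors.  `sigma = 0.2` is the noise level that
#' recapitulates human-like correlation spreads; `ptr_noise_sd = 0.06`
#' matches the in vitro stationary spread (0.059).
#'
#' @param taxon Identifier.
#' @param true_phase One of [growth_phases()].
#' @param growth A [growth_params()] object (default r 1.2, K 100,
#'   x0 1).
#' @param sigma sLGE noise magnitude (default 0.2).
#' @param ptr_intercept `b0`, log2 PTR at zero growth (default 0.30).
#' @param ptr_slope `b1 > 0`, log2 PTR per unit normalized growth rate;
#'   `NULL` (default) calibrates it to the mid-log anchor
#'   `midlog_anchor`.
#' @param ptr_noise_sd Per-sample log2 PTR noise (default 0.06).
#' @param mean_depth Expected read count at carrying capacity
#'   (default 10000).
#' @param midlog_anchor Mid-log mean log2 PTR the calibration targets
#'   (default 1.25).
#' @return An object of class `"taxon_spec"`.
#' @export
taxon_spec <- function(taxon, true_phase,
                       growth = growth_params(1.2, 100, 1),
                       sigma = 0.2, ptr_intercept = 0.30,
                       ptr_slope = NULL, ptr_noise_sd = 0.06,
                       mean_depth = 10000, midlog_anchor = 1.25) {
  true_phase <- match.arg(true_phase, growth_phases())
  growth <- as_growth_params(growth)
  stopifnot(sigma >= 0, ptr_noise_sd >= 0, mean_depth > 0)
  if (is.null(ptr_slope)) {
    b <- phase_boundaries(growth)
    # expected normalized rate over the mid-log window, uniform in time:
    # integral of dx/dt is just the abundance gain across the window
    x23 <- logistic_solution(growth, c(b$s2, b$s3))
    gbar_mid <- (x23[2] - x23[1]) /
      ((b$s3 - b$s2) * growth$r * growth$K / 4)
    ptr_slope <- (midlog_anchor - ptr_intercept) / gbar_mid
  }
  if (ptr_slope <= 0) stop("taxon_spec: ptr_slope must be > 0",
                           call. = FALSE)
  structure(list(taxon = as.character(taxon), true_phase = true_phase,
                 growth = growth, sigma = sigma,
                 ptr_intercept = ptr_intercept, ptr_slope = ptr_slope,
                 ptr_noise_sd = ptr_noise_sd, mean_depth = mean_depth),
            class = "taxon_spec")
}

#' Sample a within-curve observation time for a taxon
#'
#' Draws times uniformly from the taxon's true-phase window of its own
#' growth curve.  The window is a fixed property of the taxon (the same
#' taxon is always read in the same phase across stool days); only the
#' position within the window varies.  Acceleration uses `[0, s2]`
#' (lag merged in, curve origin as the lower edge); stationary uses
#' `[s4, s4 + (s4 - s1)]`, one active-growth span deep into saturation.
#' Draws consume the current RNG state.
#'
#' @param spec A [taxon_spec()].
#' @param n Number of draws.
#' @return Numeric vector of times on the taxon's curve axis.
#' @export
sample_phase_time <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "taxon_spec"))
  b <- phase_boundaries(spec$growth)
  lim <- switch(spec$true_phase,
                acceleration = c(0, b$s2),
                midlog = c(b$s2, b$s3),
                deceleration = c(b$s3, b$s4),
                stationary = c(b$s4, b$s4 + (b$s4 - b$s1)))
  stats::runif(n, lim[1], lim[2])
}

#' Simulate one taxon's longitudinal record
#'
#' For each stool day, one independent sLGE path is run up to a time
#' drawn by [sample_phase_time()] and read out there: the abundance `x`
#' yields counts `~ Poisson(mean_depth * x / K)` and the normalized
#' effective growth rate `g = r x (1 - x/K) / (rK/4)` yields
#' `log2ptr = b0 + b1 g + noise`.  Each cell of the PTR record is
#' dropped (set `NA`) with probability `ptr_missing`, mimicking the
#' sporadic missingness of replication-rate estimators.
#'
#' @param spec A [taxon_spec()].
#' @param days Strictly increasing integer collection days.
#' @param seed Integer seed (one per taxon; the donor generator derives
#'   these from its own seed).
#' @param ptr_missing Probability a PTR value is missing (default 0).
#' @return List with `counts`, `log2ptr`, `x`, `times` (per day), and
#'   `truth` (one-row data frame recording the spec).
#' @export
generate_taxon_series <- function(spec, days, seed = 42L,
                                  ptr_missing = 0) {
  stopifnot(inherits(spec, "taxon_spec"), length(days) >= 1L,
            all(diff(days) > 0))
  m <- length(days)
  gp <- spec$growth
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  tau <- sample_phase_time(spec, m)
  # one sLGE path per stool day, read at that day's sampled time
  cfg <- slge_config(gp, sigma = spec$sigma, t0 = 0,
                     t_final = max(tau) + 1e-9 + 0.01, n_steps = 100,
                     n_iter = m, seed = seed + 1L)
  ens <- simulate_slge(cfg)
  idx <- vapply(tau, function(t) which.min(abs(ens$times - t)),
                integer(1))
  x <- ens$abundances[cbind(seq_len(m), idx)]
  # replication state is set by the position on the growth curve; the
  # sLGE noise on x represents ecological/observational abundance
  # fluctuation that does not re-enter the replication machinery
  g <- logistic_rate(gp, tau) / (gp$r * gp$K / 4)
  counts <- stats::rpois(m, spec$mean_depth * x / gp$K)
  log2ptr <- spec$ptr_intercept + spec$ptr_slope * g +
    stats::rnorm(m, 0, spec$ptr_noise_sd)
  if (ptr_missing > 0) {
    log2ptr[stats::runif(m) < ptr_missing] <- NA_real_
  }
  truth <- data.frame(taxon = spec$taxon, true_phase = spec$true_phase,
                      r = gp$r, K = gp$K, x0 = gp$x0,
                      sigma = spec$sigma,
                      ptr_intercept = spec$ptr_intercept,
                      ptr_slope = spec$ptr_slope,
                      ptr_noise_sd = spec$ptr_noise_sd,
                      mean_depth = spec$mean_depth,
                      stringsAsFactors = FALSE)
  list(counts = counts, log2ptr = log2ptr, x = x, times = tau,
       truth = truth)
}

#' Specification of a synthetic donor
#'
#' A donor is a set of [taxon_spec()]s observed on a shared stool
#' sampling calendar of 3-5 collection days per week (so day gaps of
#' 1-3 days occur, exercising the delta day-gap gate on realistic
#' spacing).  The default donor carries 12 taxa, three per growth phase,
#' with maximal growth rates and sequencing depths varied across taxa.
#'
#' @param donor Donor identifier.
#' @param taxa List of [taxon_spec()]s; `NULL` for the 12-taxon default.
#' @param n_timepoints Number of stool samples (default 60, >= 10).
#' @param seed Integer seed controlling calendar, simulation and noise.
#' @param ptr_missing Per-cell PTR missingness probability
#'   (default 0.1).
#' @return An object of class `"donor_spec"`.
#' @export
donor_spec <- function(donor = "synthA", taxa = NULL, n_timepoints = 60L,
                       seed = 42L, ptr_missing = 0.1) {
  stopifnot(n_timepoints >= 10L, ptr_missing >= 0, ptr_missing < 1)
  if (is.null(taxa)) {
    taxa <- list()
    rs <- c(0.8, 1.2, 1.6)
    depths <- c(5000, 10000, 20000)
    i <- 0L
    for (phase in growth_phases()) {
      for (j in 1:3) {
        i <- i + 1L
        taxa[[i]] <- taxon_spec(sprintf("taxon_%s_%d", phase, j), phase,
                                growth = growth_params(rs[j], 100, 1),
                                mean_depth = depths[j])
      }
    }
  }
  stopifnot(all(vapply(taxa, inherits, logical(1), "taxon_spec")))
  structure(list(donor = as.character(donor), taxa = taxa,
                 n_timepoints = as.integer(n_timepoints),
                 seed = as.integer(seed), ptr_missing = ptr_missing),
            class = "donor_spec")
}

# 3-5 collection days per week until n samples are reached
sample_calendar <- function(n) {
  days <- integer(0)
  week <- 0L
  while (length(days) < n) {
    k <- sample(3:5, 1L)
    days <- c(days, sort(sample(0:6, k)) + 7L * week)
    week <- week + 1L
  }
  days[seq_len(n)]
}

#' Generate a full synthetic donor data set
#'
#' Simulates every taxon of a [donor_spec()] on a shared stool calendar
#' and assembles the three pipeline input tables - a counts matrix
#' (taxa x samples), a log2(PTR) matrix with missing cells, and sample
#' metadata (sample id, donor id, day) - plus the ground-truth table.
#' With `outdir` set, the tables are written in the exact dialects the
#' readers expect (`abundance.tsv`, `ptr.csv`, `meta.tsv`, `truth.tsv`);
#' outputs are fully determined by the spec's seed.
#'
#' @param spec A [donor_spec()].
#' @param outdir Directory to write the four files into (created if
#'   needed), or `NULL` (default) to return tables in memory only.
#' @return List with `counts` (integer matrix), `ptr` (numeric matrix),
#'   `metadata` (data frame), `truth` (data frame), and `paths` (named
#'   character vector when `outdir` is given).
#' @examples
#' d <- generate_donor(donor_spec(n_timepoints = 20, seed = 1))
#' dim(d$counts)
#' @export
generate_donor <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "donor_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)
  days <- sample_calendar(spec$n_timepoints)
  taxon_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(spec$taxa))
  sims <- Map(function(ts, sd) {
    generate_taxon_series(ts, days, seed = sd,
                          ptr_missing = spec$ptr_missing)
  }, spec$taxa, as.list(taxon_seeds))

  sample_ids <- sprintf("S%03d", seq_along(days))
  counts <- do.call(rbind, lapply(sims, `[[`, "counts"))
  ptr <- do.call(rbind, lapply(sims, `[[`, "log2ptr"))
  taxa_ids <- vapply(spec$taxa, `[[`, character(1), "taxon")
  dimnames(counts) <- dimnames(ptr) <- list(taxa_ids, sample_ids)
  storage.mode(counts) <- "integer"
  metadata <- data.frame(sample_id = sample_ids, donor_id = spec$donor,
                         day = days, stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  truth$donor <- spec$donor
  rownames(truth) <- NULL

  out <- list(counts = counts, ptr = ptr, metadata = metadata,
              truth = truth)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    paths <- c(abundance = file.path(outdir, "abundance.tsv"),
               ptr = file.path(outdir, "ptr.csv"),
               meta = file.path(outdir, "meta.tsv"),
               truth = file.path(outdir, "truth.tsv"))
    write_counts_table(counts, paths[["abundance"]])
    write_ptr_table(ptr, paths[["ptr"]])
    utils::write.table(metadata, paths[["meta"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
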