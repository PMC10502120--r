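test_that("CLR transform centers samples and honors its identities", {
  # uniform composition maps to zero
  expect_equal(unname(clr_transform(cbind(rep(5, 4)), pseudocount = 0)),
               cbind(rep(0, 4)))
  # hand-computed two-taxon case: ln2 - (ln2 + ln8)/2 = -ln2
  expect_equal(unname(clr_transform(cbind(c(2, 8)), pseudocount = 0)),
               cbind(c(-log(2), log(2))), tolerance = 1e-12)

  set.seed(3)
  m <- matrix(rpois(60, 50), nrow = 6)
  clr <- clr_transform(m)
  expect_true(all(abs(colSums(clr)) < 1e-10))
  # scale invariance of a sample's composition (pseudocount 0 so the
  # perturbation is exactly multiplicative)
  m2 <- m + 1
  expect_equal(clr_transform(7 * m2, pseudocount = 0),
               clr_transform(m2, pseudocount = 0), tolerance = 1e-12)
})

test_that("CLR agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(rpois(80, 30), nrow = 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  ref <- t(vegan::decostand(t(m), method = "clr", pseudocount = 0.5))
  expect_equal(unclass(clr_transform(m, pseudocount = 0.5)),
               unclass(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("CLR rejects malformed input naming the offender", {
  expect_error(clr_transform(cbind(c(1, 2), c(-1, 2))), "non-negative")
  expect_error(clr_transform(cbind(ok = c(1, 2), bad = c(0, 0)),
                             pseudocount = 0),
               "bad")
  expect_error(clr_transform(cbind(5)), "2 taxa")
})

test_that("delta computation applies the strict day-gap gate", {
  s <- taxon_series("t", "d", c(1, 2, 3), c(3, 5, 4), c(NA, NA, NA))
  d <- compute_deltas(s)
  expect_equal(d$abundance, c(3, 5))
  expect_equal(d$delta, c(2, -1))
  # a 4-day gap is dropped entirely
  s2 <- taxon_series("t", "d", c(1, 5), c(0, 1), c(NA, NA))
  expect_identical(nrow(compute_deltas(s2)), 0L)
  # a 2-day gap passes the < 3 rule
  s3 <- taxon_series("t", "d", c(1, 3), c(0, 1), c(NA, NA))
  expect_equal(compute_deltas(s3), data.frame(abundance = 0, delta = 1))
  # gap = max_gap exactly is excluded (strict), and output never
  # exceeds n - 1 pairs
  s4 <- taxon_series("t", "d", c(1, 4, 5, 8, 9), rnorm(5), rep(NA, 5))
  expect_identical(nrow(compute_deltas(s4)), 2L)
})

test_that("delta-vs-abundance statistics capture regression to the mean", {
  # alternating series: deltas are an exact negative affine map
  s <- taxon_series("t", "d", 1:5, c(1, 2, 1, 2, 1), rep(NA, 5))
  st <- delta_abundance_stats(compute_deltas(s))
  expect_equal(st$pearson_r, -1, tolerance = 1e-12)
  expect_equal(st$slope, -2, tolerance = 1e-12)

  # iid sampling from a stationary distribution: corr(x, x' - x) has
  # expectation -1/sqrt(2)
  set.seed(14)
  s2 <- taxon_series("t", "d", 1:500, rnorm(500), rep(NA, 500))
  st2 <- delta_abundance_stats(compute_deltas(s2))
  expect_equal(st2$pearson_r, -1 / sqrt(2), tolerance = 0.08)

  expect_identical(
    delta_abundance_stats(data.frame(abundance = c(1, 2),
                                     delta = c(0, 0)))$status,
    "too_few_points")
  expect_identical(
    delta_abundance_stats(data.frame(abundance = rep(1, 5),
                                     delta = rnorm(5)))$status,
    "zero_variance")
})

test_that("sLGE stationary sampling shows the negative delta signature", {
  # daily-style reads from the stationary window of stochastic paths
  gp <- growth_params(1.2, 100, 1)
  ens <- simulate_slge(slge_config(gp, sigma = 0.1, seed = 31))
  b <- phase_boundaries(gp, t0 = 1)
  keep <- which(ens$times >= b$s4 + 1 &
                  abs(ens$times %% 1) < 1e-9)  # unit spacing, > 50 pts
  expect_gt(length(keep), 50)
  rs <- apply(ens$abundances[, keep], 1, function(x) {
    d <- diff(x)
    cor(x[-length(x)], d)
  })
  expect_gte(mean(rs < 0), 0.95)
})

test_that("PTR-abundance regression enforces the > 5 matched point rule", {
  s <- taxon_series("t", "d", 1:6, c(1, 2, 3, 4, 5, 6) / 2,
                    c(1, 2, 3, 4, 5, 6) / 2)
  st <- ptr_abundance_regression(s)
  expect_equal(st$slope, 1, tolerance = 1e-12)
  expect_equal(st$pearson_r, 1, tolerance = 1e-12)
  expect_lt(st$p, 0.05)

  s_const <- taxon_series("t", "d", 1:6, rnorm(6), rep(0.5, 6))
  expect_identical(ptr_abundance_regression(s_const)$status,
                   "zero_variance")

  # exactly 5 matched points: ineligible (strictly more than 5 needed)
  s5 <- taxon_series("t", "d", 1:6, rnorm(6),
                     c(NA, 0.1, 0.5, 0.3, 0.2, 0.4))
  expect_identical(ptr_abundance_regression(s5)$status, "ineligible")
})

test_that("BH adjustment matches the brute-force definition exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_identical(q, brute_force_bh(p))
    expect_true(all(q >= p) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher's method reproduces its worked example and closed form", {
  # the four donor-level p-values combine to 0.005
  expect_equal(round(fisher_combine(c(0.0318, 0.125, 0.155, 0.031)), 3),
               0.005)
  # two inputs: closed form exp(-X/2) (1 + X/2) at df = 4
  set.seed(2)
  for (i in 1:25) {
    p2 <- runif(2, 1e-6, 1)
    X <- -2 * sum(log(p2))
    expect_equal(fisher_combine(p2), exp(-X / 2) * (1 + X / 2),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_identical(fisher_combine(c(1, 1, 1)), 1)
  expect_error(fisher_combine(c(0, 0.5)), "infinite")
  expect_error(fisher_combine(c(0.5, 1.5)), "\\(0, 1\\]")
})

test_that("ADF screen has power against AR(1) and near-nominal null size", {
  set.seed(52)
  ar_flags <- replicate(100, {
    adf_stationarity(as.numeric(arima.sim(list(ar = 0.5), 300)))$stationary
  })
  expect_gte(sum(ar_flags), 95)

  rw <- replicate(300, {
    adf_stationarity(cumsum(rnorm(300)))$stationary
  })
  # unit-root null: flags occur at roughly the 10% significance level
  expect_lt(mean(rw), 0.16)

  # the p < 0.1 rule: significant p means stationary
  res <- adf_stationarity(as.numeric(arima.sim(list(ar = 0.5), 300)))
  expect_identical(res$stationary, res$p < 0.1)
  expect_identical(adf_stationarity(rnorm(10))$status, "too_short")
  expect_identical(adf_stationarity(rep(2, 50))$status, "constant")
})

test_that("ADF statistic agrees with the standard trend regression", {
  # fixed-lag statistic recomputed from scratch with lm()
  set.seed(6)
  y <- cumsum(rnorm(120))
  res <- adf_stationarity(y, lags = 2)
  dy <- diff(y)
  n <- length(y)
  df <- data.frame(dy = dy[3:(n - 1)], ylag = y[3:(n - 1)],
                   tt = 3:(n - 1), l1 = dy[2:(n - 2)],
                   l2 = dy[1:(n - 3)])
  fit <- lm(dy ~ tt + ylag + l1 + l2, data = df)
  expect_equal(res$statistic,
               summary(fit)$coefficients["ylag", "t value"],
               tolerance = 1e-8)
})

test_that("donor-level mean regression recovers engineered structure", {
  set.seed(9)
  mk <- function(i, b) {
    ptr <- rnorm(10, i / 2, 0.01)
    taxon_series(paste0("t", i), "d", 1:10,
                 b * ptr + rnorm(10, 0, 1e-4), ptr)
  }
  series <- lapply(1:8, mk, b = 2)
  st <- donor_mean_regression(series)
  expect_equal(st$slope, 2, tolerance = 1e-2)
  expect_identical(st$n, 8L)

  # shuffled pairing destroys the association
  set.seed(10)
  shuffled <- lapply(1:50, function(i) {
    taxon_series(paste0("t", i), "d", 1:10, rnorm(10, rnorm(1)),
                 rnorm(10, rnorm(1)))
  })
  st2 <- donor_mean_regression(shuffled)
  expect_lt(abs(st2$pearson_r), 0.3)
  expect_identical(donor_mean_regression(series[1:2])$status,
                   "too_few_taxa")

  # composition contract: donor p-values feed Fisher's method
  ps <- replicate(4, donor_mean_regression(series)$p)
  expect_true(fisher_combine(ps) >= 0 && fisher_combine(ps) <= 1)
})

test_that("taxonomy covariates rescue the within-group slope", {
  # Simpson's paradox fixture: identical positive within-group slopes,
  # opposing group means
  set.seed(20)
  n <- 40
  g1 <- data.frame(clr = rnorm(n, 5), group = "a")
  g2 <- data.frame(clr = rnorm(n, -5), group = "b")
  d <- rbind(g1, g2)
  d$log2ptr <- 0.5 * d$clr + ifelse(d$group == "a", -6, 6) +
    rnorm(2 * n, 0, 0.1)
  naive <- coef(lm(log2ptr ~ clr, data = d))["clr"]
  expect_lt(naive, 0)  # pooled fit reverses the sign
  adj <- covariate_adjusted_regression(d)
  expect_equal(adj$slope, 0.5, tolerance = 0.05)
  expect_lt(adj$p, 1e-6)

  # normal-equations oracle on the same design matrix
  X <- cbind(1, d$clr, d$group == "b")
  beta <- solve(crossprod(X), crossprod(X, d$log2ptr))
  expect_equal(adj$slope, beta[2], tolerance = 1e-10)

  # orthogonal indicators leave the simple slope untouched
  d2 <- data.frame(clr = rep(c(-1, 1), 50),
                   group = rep(c("a", "b"), each = 50))
  d2$clr <- d2$clr - mean(d2$clr)
  set.seed(21)
  d2$log2ptr <- 0.3 * d2$clr + rnorm(100, 0, 0.05)
  d2$clr <- rep(seq(-1, 1, length.out = 50), 2)  # same within groups
  d2$log2ptr <- 0.3 * d2$clr + rnorm(100, 0, 0.05)
  adj2 <- covariate_adjusted_regression(d2)
  simple2 <- coef(lm(log2ptr ~ clr, data = d2))["clr"]
  expect_equal(adj2$slope, unname(simple2), tolerance = 1e-8)

  expect_warning(
    covariate_adjusted_regression(data.frame(clr = rnorm(10),
                                             log2ptr = rnorm(10),
                                             group = "only")),
    "single taxon group")
})

test_that("covariate model recovers a weak planted slope", {
  # a single fit lands within 2 SE only ~95% of the time, so check the
  # coverage across replicate cohorts
  set.seed(33)
  covered <- replicate(20, {
    groups <- rep(letters[1:6], each = 50)
    clr <- rnorm(300, rep(rnorm(6, 0, 2), each = 50))
    log2ptr <- 0.05 * clr + rep(rnorm(6, 0.6, 0.3), each = 50) +
      rnorm(300, 0, 0.1)
    adj <- covariate_adjusted_regression(
      data.frame(clr = clr, log2ptr = log2ptr, group = groups))
    se <- summary(adj$fit)$coefficients["clr", "Std. Error"]
    abs(adj$slope - 0.05) < 2 * se
  })
  expect_gte(sum(covered), 17)
})
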