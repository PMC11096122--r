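test_that("concordance filters apply the three rules as stated", {
  mkSe <- function(h, alt) list(
    heteroplasmy = matrix(h, 1, length(h),
                          dimnames = list("v1", paste0("c", seq_along(h)))),
    alt = matrix(alt, 1, length(alt),
                 dimnames = list("v1", paste0("c", seq_along(h)))))
  # all kept: alt >= 10, window respected, range 0.2 >= 0.15
  keep <- concordanceFilters(mkSe(c(0.1, 0.2, 0.3), c(12, 15, 20)))
  expect_equal(nrow(keep), 3)
  expect_equal(keep$h, c(0.1, 0.2, 0.3))
  # window drops 0.04 and 0.96; remaining single point has range 0
  drop1 <- concordanceFilters(mkSe(c(0.04, 0.5, 0.96), c(20, 20, 20)))
  expect_equal(nrow(drop1), 0)
  expect_equal(attr(drop1, "dropped")$reason, "range_below_minimum")
  # window endpoints are retained (h < lo or h > hi are dropped)
  edge <- concordanceFilters(mkSe(c(0.05, 0.95), c(20, 20)))
  expect_equal(sort(edge$h), c(0.05, 0.95))
  # alt-read threshold removes everything
  drop2 <- concordanceFilters(mkSe(c(0.2, 0.3, 0.4), c(9, 9, 9)))
  expect_equal(nrow(drop2), 0)
  expect_equal(attr(drop2, "dropped")$reason, "no_observations")
})

test_that("single-stratum concordance matches brute-force pair counting", {
  perfect <- stratifiedConcordance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect@c, 1)
  expect_equal(perfect@cScaled, 1)
  reversed <- stratifiedConcordance(c(1, 2, 3), c(3, 2, 1))
  expect_equal(reversed@c, 0)
  expect_equal(reversed@cScaled, -1)
  # 6 pairs, 1 discordant -> c = 5/6
  mixed <- stratifiedConcordance(1:4, c(1, 3, 2, 4))
  expect_equal(mixed@c, 5 / 6)
  expect_equal(mixed@cScaled, 2 / 3)
  expect_equal(mixed@z, (5 / 6 - 0.5) / sqrt(mixed@variance))
  # degenerate: single observation per stratum
  deg <- stratifiedConcordance(1, 1, stratum = "a")
  expect_true(is.na(deg@c))
  expect_equal(deg@reason, "all_strata_degenerate")
})

test_that("with no ties c_scaled equals Kendall tau-a and is rank invariant", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    h <- rnorm(n); y <- rnorm(n)
    res <- stratifiedConcordance(h, y)
    expect_equal(res@cScaled, cor(h, y, method = "kendall"),
                 tolerance = 1e-12)
    # invariance to strictly monotone transforms
    res2 <- stratifiedConcordance(exp(h), y^3 + 5 * y)
    expect_equal(res2@cScaled, res@cScaled, tolerance = 1e-12)
  }
})

test_that("stratified weighting combines per-stratum concordances as stated", {
  h <- c(1, 2, 3, 1, 2, 3, 4)
  y <- c(1, 2, 3, 4, 3, 2, 1)      # stratum A perfect, stratum B reversed
  s <- c("A", "A", "A", "B", "B", "B", "B")
  w <- c(30, 30, 30, 10, 10, 10, 10)
  res <- stratifiedConcordance(h, y, s, w)
  expect_equal(res@nStrata, 2L)
  expect_equal(res@c, (30 * 1 + 10 * 0) / 40)
  varA <- 2 * (2 * 3 + 5) / (9 * 3 * 2) / 4
  varB <- 2 * (2 * 4 + 5) / (9 * 4 * 3) / 4
  expect_equal(res@variance, (30^2 * varA + 10^2 * varB) / 40^2)
})

test_that("unweighted concordance agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    h <- rnorm(n); y <- rnorm(n)
    ours <- stratifiedConcordance(h, y)@c
    ref <- survival::concordance(y ~ h)$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("analytic p values are calibrated against the permutation null", {
  set.seed(55)
  h <- runif(40); y <- runif(40)             # null
  pn <- permutationNull(h, y, nPerm = 1000, seed = 7)
  se <- sqrt(pn$p * (1 - pn$p) / 1000)
  expect_lt(abs(pn$p - pn$observed@p), 3 * se + 1e-9)
  # strongly concordant data: tiny p in both
  hc <- seq(0, 1, length.out = 12)
  pn2 <- permutationNull(hc, hc + rnorm(12, 0, 0.01), nPerm = 999,
                         seed = 8)
  expect_lte(pn2$p, 0.02)
  expect_lt(pn2$observed@p, 0.01)
  expect_error(permutationNull(h, y, nPerm = 50), "at least 100")
})

test_that("BH adjustment equals the hand step-up computation and preserves order", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  # hand computation: sorted (.005,.03,.04,.8) -> step-up
  # (.02, .06, .0533.., .8) -> monotone (.02, .0533.., .0533.., .8)
  expect_equal(bhAdjust(c(0.005, 0.04, 0.03, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  # permutation equivariance
  p <- c(0.009, 0.21, 0.04, 0.8, 0.001)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_error(bhAdjust(c(0.5, 1.2)), "0,1")
})

test_that("concordance table runs per variant with BH across variants", {
  obs <- rbind(
    data.frame(variant = "v1", h = 1:6, y = 1:6,
               stratum = "a", weight = 6),
    data.frame(variant = "v2", h = 1:6, y = c(2, 1, 4, 3, 6, 5),
               stratum = "a", weight = 6))
  tab <- concordanceTable(obs)
  expect_equal(tab$variant, c("v1", "v2"))
  expect_equal(tab$c[1], 1)
  expect_equal(tab$q, bhAdjust(tab$p))
})

test_that("size regression recovers exact lines and flags degenerate libraries", {
  d <- data.frame(library_id = "L1", diameter_um = c(10, 20, 30, 40),
                  cn = 24 * c(10, 20, 30, 40), average_ploidy = 2)
  sr <- sizeRegression(d)
  expect_equal(sr$slope, 24)
  expect_equal(sr$intercept, 0, tolerance = 1e-9)
  expect_equal(sr$r, 1)
  # 3 collinear points: p floored at the smallest representable double
  d2 <- data.frame(library_id = "L1", diameter_um = 1:3, cn = 10 * (1:3),
                   average_ploidy = 2)
  sr2 <- sizeRegression(d2)
  expect_equal(sr2$slope, 10)
  expect_gt(sr2$p, 0)
  # constant diameter -> flagged
  d3 <- data.frame(library_id = "L1", diameter_um = rep(5, 4),
                   cn = c(1, 2, 3, 4), average_ploidy = 2)
  expect_true(sizeRegression(d3)$flagged)
  # shuffled diameters: correlation centred at zero over seeds
  set.seed(33)
  rs <- replicate(50, {
    cn <- rlnorm(40, 6, 0.5)
    sizeRegression(data.frame(library_id = "L", cn = cn,
                              diameter_um = sample(cn),
                              average_ploidy = 2))$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})
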