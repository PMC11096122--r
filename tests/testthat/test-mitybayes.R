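test_that("input validation rejects impossible instances", {
  total <- matrix(10L, 3, 2)
  expect_error(fitMityBayes(matrix(11L, 3, 2), total, K = 1), "exceed")
  expect_error(fitMityBayes(matrix(1L, 3, 2), total, K = 4), "cells")
  expect_error(fitMityBayes(matrix(1L, 3, 2), total, K = 0), ">= 1")
  expect_error(mbPriors(alpha = 0), "> 0")
  expect_error(mbPriors(fixedPi = c(0.5, 0.6)), "simplex")
})

test_that("K=1 recovers the pooled Beta-binomial posterior mode", {
  alt <- rbind(c(3L, 7L), c(5L, 2L))
  total <- matrix(10L, 2, 2)
  fit <- fitMityBayes(alt, total, K = 1, priors = mbPriors(a = 2, b = 2),
                      nRestarts = 1, seed = 1)
  expected <- (colSums(alt) + 2 - 1) / (colSums(total) + 2 + 2 - 2)
  expect_equal(as.vector(fit@P), expected, tolerance = 1e-6)
  expect_equal(as.vector(fit@gamma), c(1, 1))
})

test_that("two opposite cells separate into two clones with near-certain assignment", {
  alt <- rbind(10L, 0L); total <- rbind(10L, 10L)
  fit <- fitMityBayes(alt, total, K = 2, nRestarts = 4, seed = 1)
  expect_true(all(apply(fit@gamma, 1, max) > 0.99))
  lab <- apply(fit@gamma, 1, which.max)
  expect_equal(length(unique(lab)), 2)
  Pord <- sort(as.vector(fit@P))
  expect_lt(Pord[1], 0.05)
  expect_gt(Pord[2], 0.95)
  # exact enumeration finds the same MAP partition
  ex <- exactPosterior(alt, total, K = 2, canonical = TRUE)
  expect_equal(length(unique(ex$mapAssignment)), 2)
})

test_that("the objective trace is nondecreasing and backends agree", {
  d <- simMbScenario(40, 4, 2, 40, seed = 11)
  em <- fitMityBayes(d$alt, d$total, K = 2, backend = "em",
                     nRestarts = 3, seed = 5)
  expect_true(all(diff(em@elboTrace) >= -1e-8))
  gr <- fitMityBayes(d$alt, d$total, K = 2, backend = "gradient",
                     nRestarts = 3, seed = 5, maxIter = 2000L)
  expect_true(all(diff(gr@elboTrace) >= -1e-8))
  expect_lt(abs(max(em@elboTrace) - max(gr@elboTrace)) /
              abs(max(em@elboTrace)), 1e-3)
  emLab <- apply(em@gamma, 1, which.max)
  grLab <- apply(gr@gamma, 1, which.max)
  expect_equal(mclust::adjustedRandIndex(emLab, grLab), 1)
})

test_that("the fit is invariant to clone label permutation of the data-generating process", {
  d <- simMbScenario(60, 6, 3, 40, seed = 21)
  f1 <- fitMityBayes(d$alt, d$total, K = 3, nRestarts = 4, seed = 9)
  f2 <- fitMityBayes(d$alt, d$total, K = 3, nRestarts = 4, seed = 10)
  # different restart streams must land on the same partition & objective
  expect_lt(abs(max(f1@elboTrace) - max(f2@elboTrace)) /
              abs(max(f1@elboTrace)), 1e-4)
  expect_equal(mclust::adjustedRandIndex(
    apply(f1@gamma, 1, which.max), apply(f2@gamma, 1, which.max)), 1)
  # determinism: same seed -> identical model
  f3 <- fitMityBayes(d$alt, d$total, K = 3, nRestarts = 4, seed = 9)
  expect_identical(f1@P, f3@P)
  expect_identical(f1@elboTrace, f3@elboTrace)
})

test_that("clone assignment applies the probability floor with index tie-break", {
  model <- new("CloneModel", K = 2L,
               pi = c(0.5, 0.5), P = matrix(0.5, 2, 1),
               gamma = rbind(c(0.99, 0.01), c(0.5, 0.5), c(0.4, 0.6)),
               contribution = 0, elboTrace = 0, converged = TRUE,
               backend = "em", seed = 1L,
               alt = matrix(0, 3, 1), total = matrix(0, 3, 1))
  expect_equal(assignClones(model, 0.9),
               c("1", "unassigned", "unassigned"))
  expect_equal(assignClones(model, 0.5), c("1", "1", "2"))
})

test_that("variant contribution ranks clone-separating variants above constant ones", {
  # variant 1 separates perfectly, variant 2 is constant across clones
  d <- simMbScenario(40, 1, 2, 60, seed = 31)
  alt <- cbind(d$alt, rbinom(40, 60, 0.5))
  total <- cbind(d$total, rep(60L, 40))
  fit <- fitMityBayes(alt, total, K = 2, nRestarts = 3, seed = 2)
  expect_gt(fit@contribution[1], fit@contribution[2])
  expect_equal(fit@contribution[2], 0)    # min-max rescaling floor
  expect_equal(fit@contribution[1], 1)
  # identical copies of one variant get equal weights
  alt3 <- cbind(d$alt, d$alt, d$alt)
  tot3 <- cbind(d$total, d$total, d$total)
  f3 <- fitMityBayes(alt3, tot3, K = 2, nRestarts = 3, seed = 2)
  expect_lt(diff(range(f3@contribution)), 1e-6)
})

test_that("exact enumeration respects symmetry, size caps and the no-data case", {
  # single cell, symmetric priors: marginals are uniform
  ex <- exactPosterior(matrix(5L, 1, 1), matrix(10L, 1, 1), K = 2)
  expect_equal(as.vector(ex$gamma), c(0.5, 0.5))
  # no data: posterior equals the (symmetric) prior
  ex0 <- exactPosterior(matrix(0L, 3, 2), matrix(0L, 3, 2), K = 2,
                        priors = mbPriors(fixedPi = c(0.5, 0.5)))
  expect_equal(ex0$gamma, matrix(0.5, 3, 2))
  expect_error(exactPosterior(matrix(0L, 9, 1), matrix(0L, 9, 1), K = 2),
               "caps")
  expect_error(exactPosterior(matrix(0L, 2, 5), matrix(0L, 2, 5), K = 2),
               "caps")
})

test_that("fit agrees with the exact oracle on all instances within its caps", {
  instances <- list(
    list(alt = rbind(10L, 0L), total = rbind(10L, 10L), K = 2),
    list(alt = rbind(c(18L, 2L), c(17L, 1L), c(2L, 18L),
                     c(1L, 19L), c(2L, 17L), c(18L, 3L)),
         total = matrix(20L, 6, 2), K = 2),
    list(alt = rbind(c(19L, 1L, 1L), c(18L, 2L, 1L), c(1L, 18L, 2L),
                     c(2L, 19L, 1L), c(1L, 2L, 18L)),
         total = matrix(20L, 5, 3), K = 3),
    list(alt = rbind(c(15L, 0L), c(14L, 1L), c(16L, 2L), c(13L, 0L),
                     c(0L, 15L), c(1L, 16L), c(2L, 14L), c(0L, 13L)),
         total = matrix(20L, 8, 2), K = 2))
  for (ins in instances) {
    ex <- exactPosterior(ins$alt, ins$total, K = ins$K, canonical = TRUE)
    fit <- fitMityBayes(ins$alt, ins$total, K = ins$K, nRestarts = 6,
                        seed = 3)
    fitLab <- apply(fit@gamma, 1, which.max)
    expect_true(samePartition(fitLab, unname(ex$mapAssignment)))
    aligned <- alignGamma(fit@gamma, ex$gamma)
    expect_lt(max(abs(aligned - ex$gamma)), 0.02)
  }
})

test_that("parameter recovery and K selection succeed on well-separated clones", {
  d <- simMbScenario(200, 10, 3, 50, seed = 41)
  fit <- fitMityBayes(d$alt, d$total, K = 3, nRestarts = 4, seed = 4)
  lab <- apply(fit@gamma, 1, which.max)
  expect_gte(mclust::adjustedRandIndex(lab, d$z), 0.9)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                c(3,2,1))
  rmse <- min(vapply(perms, function(p)
    sqrt(mean((fit@P[p, ] - d$P)^2)), 0))
  expect_lte(rmse, 0.05)
  sel <- selectK(d$alt, d$total, Kgrid = 1:4, nRestarts = 3, seed = 4)
  expect_equal(sel$K, 3)
  expect_equal(nrow(sel$table), 4)
  # single-clone data chooses K = 1; a singleton grid returns it
  d1 <- simMbScenario(80, 6, 1, 50, seed = 43)
  expect_equal(selectK(d1$alt, d1$total, Kgrid = 1:3, nRestarts = 3,
                       seed = 5)$K, 1)
  one <- selectK(d$alt, d$total, Kgrid = 1, nRestarts = 2, seed = 6)
  expect_equal(one$K, 1)
  expect_equal(nrow(one$table), 1)
})
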