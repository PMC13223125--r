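# small separable benchmark shared by the selection tests
skoaBench <- function(n = 300, p = 100, nCausal = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(2, nCausal), rep(0, p - nCausal))
  y <- as.integer(X %*% beta + rnorm(n, sd = 0.5) > 0)
  list(X = X, y = y, causal = seq_len(nCausal))
}

test_that("initialization is uniform within bounds and seed-deterministic", {
  s1 <- skoaInitialize(a = 50, k = 20, lb = -1, ub = 2, seed = 4)
  s2 <- skoaInitialize(a = 50, k = 20, lb = -1, ub = 2, seed = 4)
  expect_identical(s1$E, s2$E)
  expect_true(all(s1$E >= -1 & s1$E <= 2))
  big <- skoaInitialize(a = 500, k = 20, lb = 0, ub = 1, seed = 9)
  expect_true(all(big$E >= 0 & big$E <= 1))
  expect_gt(mean(big$E), 0.45); expect_lt(mean(big$E), 0.55)
  expect_error(skoaInitialize(a = 5, k = 2, lb = 1, ub = 1, seed = 1),
               "lb must be")
})

test_that("binarization selects strictly above 0.5 with a degeneracy guard", {
  expect_equal(binarizeMask(c(0.7, 0.3, 0.9)), c(TRUE, FALSE, TRUE))
  m <- binarizeMask(rep(0.2, 5))
  expect_equal(sum(m), 1)
  expect_true(m[which.max(rep(0.2, 5))])
  expect_equal(binarizeMask(c(0.5, 0.6)), c(FALSE, TRUE))
})

test_that("fitness is chance-level on shuffled labels and high on separable data", {
  b <- skoaBench()
  mask <- c(rep(TRUE, 10), rep(FALSE, 90))
  f <- skoaFitness(mask, b$X, b$y)
  expect_gt(f, 0.85)
  set.seed(2)
  fShuf <- skoaFitness(mask, b$X, sample(b$y))
  expect_lt(abs(fShuf - 0.5), 0.12)
  # invariant to column order within the mask
  perm <- sample(ncol(b$X))
  maskP <- mask[perm]
  expect_equal(skoaFitness(maskP, b$X[, perm], b$y), f)
  expect_error(skoaFitness(rep(FALSE, 100), b$X, b$y))
})

test_that("Smoluchowski prey selection weights fitness through the diffusion kernel", {
  # single member: always the prey
  st <- list(E = matrix(0.5, 1, 3), fitness = 0.7, t = 1L, best = NULL)
  expect_equal(smoluchowskiSelectPrey(st), rep(0.5, 3))
  # one dominant member: selected with probability one
  st2 <- list(E = rbind(c(0, 0), c(1, 1), c(0.5, 0.5)),
              fitness = c(0, 1, 0), t = 2L, best = c(1, 1))
  set.seed(5)
  draws <- replicate(200, smoluchowskiSelectPrey(st2)[1])
  expect_true(all(draws == 1))
  # equal fitness, equal distance from the best: uniform frequencies
  stU <- list(E = rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
              fitness = rep(0.5, 4), t = 1L, best = c(0, 0))
  set.seed(6)
  picks <- replicate(10000, {
    p <- smoluchowskiSelectPrey(stU)
    which(apply(stU$E, 1, function(r) all(r == p)))
  })
  freq <- tabulate(picks, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("position updates are greedy, bounded and elitist", {
  b <- skoaBench(n = 120, p = 12, nCausal = 4)
  st <- skoaInitialize(a = 6, k = 12, seed = 3)
  st$Tmax <- 5L
  for (i in 1:6) st$fitness[i] <- skoaFitness(binarizeMask(st$E[i, ]),
                                              b$X, b$y)
  st$best <- st$E[which.max(st$fitness), ]
  st$bestFitness <- max(st$fitness)
  before <- st$bestFitness
  set.seed(11)
  st2 <- skoaStep(st, b$X, b$y)
  expect_true(all(st2$E >= 0 & st2$E <= 1))
  expect_gte(st2$bestFitness, before)
  # exploitation from the prey position is a fixed point: members equal to
  # the prey cannot move (the candidate equals the current position)
  stP <- st
  stP$E <- matrix(rep(st$best, each = 6), 6)
  for (i in 1:6) stP$fitness[i] <- skoaFitness(binarizeMask(stP$E[i, ]),
                                               b$X, b$y)
  set.seed(1)
  stP2 <- skoaStep(stP, b$X, b$y, preyFn = function(s) s$E[1, ])
  expect_equal(stP2$E, stP$E)
})

test_that("a one-iteration run equals the best of the initial population", {
  b <- skoaBench(n = 120, p = 10, nCausal = 3)
  r <- skoaRun(b$X, b$y, a = 8, Tmax = 1, seed = 2)
  st <- skoaInitialize(a = 8, k = 10, seed = 2)
  fits <- apply(st$E, 1, function(e) skoaFitness(binarizeMask(e), b$X, b$y))
  expect_gte(r$bestFitness, max(fits))
  expect_length(r$trace, 1)
})

test_that("the fitness trace is monotone and the run is seed-reproducible", {
  b <- skoaBench(n = 150, p = 20, nCausal = 5)
  r1 <- skoaRun(b$X, b$y, a = 8, Tmax = 8, seed = 5)
  r2 <- skoaRun(b$X, b$y, a = 8, Tmax = 8, seed = 5)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) >= 0))
})

test_that("SKOA recovers planted causal features (5-seed median)", {
  b <- skoaBench(n = 300, p = 100, nCausal = 10, seed = 8)
  hits <- vapply(1:5, function(s) {
    r <- skoaRun(b$X, b$y, a = 30, Tmax = 50, seed = s)
    sum(b$causal %in% r$selected)
  }, 0)
  expect_gte(median(hits), 8)
})

test_that("SKOA approaches the brute-force optimum on enumerable problems", {
  b <- skoaBench(n = 100, p = 10, nCausal = 3, seed = 12)
  allMasks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 10)))[-1, ]
  bruteBest <- max(apply(allMasks, 1, function(m)
    skoaFitness(as.logical(m), b$X, b$y)))
  gaps <- vapply(1:5, function(s) {
    r <- skoaRun(b$X, b$y, a = 30, Tmax = 50, seed = s)
    bruteBest - r$bestFitness
  }, 0)
  expect_lte(median(gaps), 0.02)
})

test_that("plain-KOA baseline runs and is comparable (reported, not asserted)", {
  b <- skoaBench(n = 150, p = 30, nCausal = 5)
  rP <- skoaRun(b$X, b$y, a = 10, Tmax = 10, seed = 3, plainKOA = TRUE)
  rS <- skoaRun(b$X, b$y, a = 10, Tmax = 10, seed = 3)
  expect_true(all(diff(rP$trace) >= 0))
  expect_true(is.finite(rP$bestFitness) && is.finite(rS$bestFitness))
})

test_that("Jaccard stability follows the set-overlap definition", {
  m1 <- c(TRUE, TRUE, TRUE, FALSE)
  m2 <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(jaccardStability(list(m1, m1)), 1)
  expect_equal(jaccardStability(list(m1, !m1)), 0)
  expect_equal(jaccardStability(list(m1, m2)), 0.5)
  e <- rep(FALSE, 4)
  expect_equal(jaccardStability(list(e, e)), 1)
  expect_equal(retentionRate(244.6, 2378), 10.29)
})
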