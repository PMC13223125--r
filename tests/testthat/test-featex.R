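test_that("decimal scaling uses the smallest adequate power of ten", {
  z <- dsScale(c(10, -100))
  expect_equal(as.numeric(z), c(0.01, -0.1))
  expect_equal(attr(z, "j"), 3)
  z2 <- dsScale(c(0.5, -0.2))
  expect_equal(as.numeric(z2), c(0.5, -0.2))
  expect_equal(attr(z2, "j"), 0)
  z3 <- dsScale(872)
  expect_equal(attr(z3, "j"), 3)
  # properties over random arrays: |out| < 1 and exact reconstruction
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(20, sd = 10^sample(-2:5, 1))
    s <- dsScale(x)
    expect_lt(max(abs(s)), 1)
    expect_equal(as.numeric(s) * 10^attr(s, "j"), x, tolerance = 1e-14)
  }
  expect_error(dsScale(c(1, NA)), "non-finite")
  expect_error(dsScale(c(1, Inf)), "non-finite")
})

test_that("tensor fusion stacks channels without mixing", {
  a <- matrix(runif(16), 4); b <- matrix(rbinom(16, 1, 0.5), 4)
  c_ <- matrix(runif(16), 4)
  tn <- fuseTensor(a, b, c_)
  expect_equal(dim(tn), c(4, 4, 3))
  expect_equal(tn[, , 1], a)
  expect_equal(tn[, , 2], b)
  expect_equal(tn[, , 3], c_)
  z <- matrix(0, 4, 4)
  expect_true(all(fuseTensor(z, z, z) == 0))
  expect_error(fuseTensor(a, matrix(0, 3, 3), c_), "mismatch")
})

test_that("GLCM features match a brute-force pair-counting oracle", {
  cst <- matrix(5, 6, 6)
  g <- glcmFeatures(cst)
  expect_equal(unname(g[grep("energy", names(g))]), rep(1, 4))
  expect_equal(unname(g[grep("contrast", names(g))]), rep(0, 4))
  # brute force on a small random image
  set.seed(9)
  img <- matrix(runif(16), 4, 4)
  nG <- 4
  got <- glcmFeatures(img, nGray = nG)
  q <- ExplainDR:::quantizeGray(img, nG)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (oi in seq_along(offs)) {
    o <- offs[[oi]]
    P <- matrix(0, nG, nG)
    for (i in 1:4) for (j in 1:4) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 >= 1 && i2 <= 4 && j2 >= 1 && j2 <= 4) {
        P[q[i, j], q[i2, j2]] <- P[q[i, j], q[i2, j2]] + 1
        P[q[i2, j2], q[i, j]] <- P[q[i2, j2], q[i, j]] + 1
      }
    }
    P <- P / sum(P)
    ii <- row(P); jj <- col(P)
    expect_equal(unname(got[grep("contrast", names(got))][oi]),
                 sum((ii - jj)^2 * P))
    expect_equal(unname(got[grep("energy", names(got))][oi]), sum(P^2))
    expect_equal(unname(got[grep("homogeneity", names(got))][oi]),
                 sum(P / (1 + (ii - jj)^2)))
  }
})

test_that("LBP histograms are uniform-59 and collapse for constant images", {
  h <- lbpFeatures(matrix(3, 5, 5))
  expect_length(h, 59)
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1)
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  expect_equal(sum(lbpFeatures(img)), 1)
  expect_error(lbpFeatures(array(0, c(2, 2, 2))), "2D")
})

test_that("local tetra patterns are deterministic 240-vectors", {
  set.seed(5)
  img <- matrix(runif(100), 10, 10)
  f1 <- ltrpFeatures(img)
  expect_length(f1, 240)
  expect_identical(f1, ltrpFeatures(img))
  expect_error(ltrpFeatures(1:10), "2D")
})

test_that("the deep extractor is deterministic with bounded scaled responses", {
  cfg <- dscnnConfig(miniMode = TRUE, seed = 3)
  params <- dscnnInit(cfg)
  set.seed(1)
  tensor <- array(runif(56 * 56 * 3), c(56, 56, 3))
  f1 <- dscnnFeatures(tensor, params)  # warm-up
  elapsed <- min(vapply(1:3, function(i) {
    t0 <- Sys.time()
    invisible(dscnnFeatures(tensor, params))
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }, 0))
  expect_lt(elapsed, 1)
  f2 <- dscnnFeatures(tensor, params)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_length(f1, cfg$penultimate)
  expect_true(all(attr(f1, "ds_max") < 1))
  # larger inputs are pooled down to the configured size
  big <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_length(dscnnFeatures(big, params), cfg$penultimate)
})

test_that("the softmax pretraining head emits probabilities summing to one", {
  set.seed(6)
  F <- matrix(rnorm(40 * 8), 40, 8)
  y <- rbinom(40, 1, 0.5)
  head_ <- dscnnTrainHead(F, y)
  P <- head_$predictProb(F)
  expect_equal(rowSums(P), rep(1, 40))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("feature assembly concatenates provenance-tagged blocks", {
  n <- 10
  mk <- function(p, pre) {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("pair", 1:n), paste0(pre, 1:p)))
    m
  }
  asm <- assembleFeatures(mk(1024, "d"), mk(354, "h"), mk(1000, "a"))
  expect_equal(ncol(asm$X), 2378)
  expect_equal(table(asm$provenance)[["deep"]], 1024)
  expect_equal(table(asm$provenance)[["handcrafted"]], 354)
  expect_equal(table(asm$provenance)[["attributes"]], 1000)
  # zero-width attribute block leaves only the deep block
  asm2 <- assembleFeatures(mk(5, "d"), NULL, NULL)
  expect_equal(ncol(asm2$X), 5)
  # misaligned rows are an error listing offending keys
  bad <- mk(3, "x"); rownames(bad)[1] <- "other"
  expect_error(assembleFeatures(mk(2, "d"), NULL, bad), "misalignment")
})

test_that("standardization uses training-row statistics only", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4, mean = 5, sd = 2), 30, 4,
              dimnames = list(paste0("p", 1:30), paste0("f", 1:4)))
  tr <- 1:20
  asm <- assembleFeatures(NULL, NULL, X, trainIdx = tr)
  expect_equal(unname(colMeans(asm$X[tr, ])), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(asm$X[tr, ], 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  # poisoning the held-out rows leaves fitted statistics untouched
  Xp <- X; Xp[21:30, ] <- Xp[21:30, ] * 1e6
  asmP <- assembleFeatures(NULL, NULL, Xp, trainIdx = tr)
  expect_identical(asm$center, asmP$center)
  expect_identical(asm$scale, asmP$scale)
  expect_identical(asm$X[tr, ], asmP$X[tr, ])
})

test_that("event-indicator maps band leaf rows by event type", {
  ev <- c("insertion", "duplication", "mirror")
  m <- makeEventMap(ev, size = 20)
  expect_true(all(m %in% c(0, 1)))
  expect_equal(sum(m[1, 1:4]), 4)    # insertion band
  expect_equal(sum(m[2, 17:20]), 4)  # duplication band
  expect_equal(sum(m[4, ]), 0)       # no fourth leaf
})
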