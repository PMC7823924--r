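test_that("Wald ratio follows the delta-method closed form", {
  e <- waldRatio(0.5, 0.05, 0.1, 0.02)
  expect_equal(mrBeta(e), 0.2)
  expect_equal(mrSE(e), 0.04)
  expect_equal(ciLower(e), 0.2 - qnorm(0.975) * 0.04)
  expect_equal(mrBeta(waldRatio(0.5, 0.05, 0, 0.02)), 0)
  expect_equal(mrBeta(waldRatio(-0.5, 0.05, 0.1, 0.02)), -0.2)
  expect_equal(mrSE(waldRatio(-0.5, 0.05, 0.1, 0.02)), 0.04)
  expect_error(waldRatio(0, 0.05, 0.1, 0.02), "zero")
})

test_that("IVW matches the hand-evaluated two-instrument case", {
  set <- makeInstruments(c(1, 1), c(0.1, 0.1), c(1, 3), c(1, 1))
  fixed <- mrIVW(set, "fixed")
  expect_equal(mrBeta(fixed), 2)
  expect_equal(mrSE(fixed), 1 / sqrt(2))
  expect_equal(fixed@qStat, 2)
  mult <- mrIVW(set)                    # overdispersion sqrt(Q/(J-1)) = sqrt(2)
  expect_equal(mrSE(mult), 1)
  expect_equal(mult@overdispersion, sqrt(2))
})

test_that("IVW with a single instrument reduces to the Wald ratio", {
  set <- makeInstruments(0.4, 0.03, 0.12, 0.05)
  iv <- mrIVW(set)
  wd <- waldRatio(0.4, 0.03, 0.12, 0.05)
  expect_equal(mrBeta(iv), mrBeta(wd))
  expect_equal(mrSE(iv), mrSE(wd))
  expect_equal(pValue(iv), pValue(wd))
})

test_that("IVW equals the fixed-effect meta-analysis of Wald ratios", {
  for (s in 1:200) {
    J <- sample(2:50, 1)
    set <- randomInstrumentSet(J, seed = s)
    ests <- lapply(seq_len(J), function(j)
      waldRatio(exposureBeta(set)[j], exposureSE(set)[j],
                outcomeBeta(set)[j], outcomeSE(set)[j]))
    ests <- lapply(ests, function(e) { e@method <- "ivw"; e })  # same scale
    meta <- metaFixed(ests)
    iv <- mrIVW(set, "fixed")
    expect_lt(abs(mrBeta(meta) - mrBeta(iv)), 1e-10)
    expect_lt(abs(mrSE(meta) - mrSE(iv)), 1e-10)
  }
})

test_that("heterogeneity Q is zero exactly on proportional instruments", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  set <- makeInstruments(g, rep(0.01, 4), 1.7 * g, rep(0.02, 4))
  iv <- mrIVW(set)
  expect_equal(iv@qStat, 0, tolerance = 1e-20)
  expect_equal(iv@overdispersion, 1)
  expect_equal(mrBeta(iv), 1.7)
})

test_that("Egger recovers an exact line and nests IVW when unintercepted", {
  g <- c(1, 2, 3)
  set <- makeInstruments(g, rep(0.05, 3), 2 * g - 1, rep(0.1, 3))
  e <- mrEgger(set)
  expect_equal(mrBeta(e$slope), 2, tolerance = 1e-12)
  expect_equal(mrBeta(e$intercept), -1, tolerance = 1e-12)

  set2 <- randomInstrumentSet(8, seed = 77)
  e0 <- mrEgger(set2, fitIntercept = FALSE)
  iv <- mrIVW(set2)
  expect_equal(mrBeta(e0$slope), mrBeta(iv), tolerance = 1e-12)
  expect_equal(mrSE(e0$slope), mrSE(iv), tolerance = 1e-12)

  expect_error(mrEgger(makeInstruments(1:2 / 10, c(0.1, 0.1),
                                       c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
  expect_error(mrEgger(makeInstruments(rep(0.2, 3), rep(0.1, 3),
                                       c(0.1, 0.2, 0.3), rep(0.1, 3))),
               "collinear")
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  set <- makeInstruments(c(1, 1, 1), c(0.01, 0.01, 0.01), c(1, 2, 3),
                         c(1, 1, 1))
  expect_equal(mrBeta(mrWeightedMedian(set, nBoot = 50)), 2)

  # weights (0.4, 0.1, 0.5) on ratios (1, 2, 3): interpolated 2 + 0.05/0.3
  w <- c(0.4, 0.1, 0.5)
  seO <- 1 / sqrt(w)                     # gamma = 1 so weight = 1/seO^2
  set2 <- makeInstruments(c(1, 1, 1), rep(0.01, 3), c(1, 2, 3), seO)
  expect_equal(mrBeta(mrWeightedMedian(set2, nBoot = 50)),
               2 + (0.5 - 0.45) / (0.75 - 0.45), tolerance = 1e-12)
  expect_error(mrWeightedMedian(makeInstruments(1, 0.1, 1, 1)), "at least 2")
})

test_that("weighted mode tracks the dominant cluster, not the outlier", {
  set <- makeInstruments(rep(1, 4), rep(0.01, 4), c(1.0, 1.01, 0.99, 5.0),
                         rep(0.05, 4))
  est <- mrBeta(mrWeightedMode(set, nBoot = 50))
  expect_lt(abs(est - 1), 0.1)

  # independent oracle: brute-force argmax of the same weighted KDE grid
  b <- c(1.0, 1.01, 0.99, 5.0)
  p <- rep(0.25, 4)
  s <- 0.9 * min(sd(b), mad(b)) * 4^(-1 / 5)
  grid <- seq(min(b) - 3 * s, max(b) + 3 * s, length.out = 512)
  dens <- sapply(grid, function(x) sum(p * dnorm(x, b, s)))
  expect_equal(est, grid[which.max(dens)])

  # degenerate spread returns the common ratio
  setEq <- makeInstruments(rep(1, 3), rep(0.01, 3), rep(0.7, 3),
                           rep(0.05, 3))
  expect_equal(mrBeta(mrWeightedMode(setEq, nBoot = 50)), 0.7)
})

test_that("estimators are equivariant under joint sign flips and reordering", {
  set <- randomInstrumentSet(9, seed = 12)
  d <- set@data
  flip <- c(2, 5, 7)
  d2 <- d
  d2$betaExposure[flip] <- -d2$betaExposure[flip]
  d2$betaOutcome[flip] <- -d2$betaOutcome[flip]
  setFlip <- new("MRInstruments", data = d2)
  expect_equal(mrBeta(mrIVW(setFlip)), mrBeta(mrIVW(set)))
  expect_equal(mrSE(mrIVW(setFlip)), mrSE(mrIVW(set)))
  expect_equal(mrBeta(mrEgger(setFlip)$slope), mrBeta(mrEgger(set)$slope))
  expect_equal(mrBeta(mrWeightedMedian(setFlip, nBoot = 10)),
               mrBeta(mrWeightedMedian(set, nBoot = 10)))
  expect_equal(mrBeta(mrWeightedMode(setFlip, nBoot = 10)),
               mrBeta(mrWeightedMode(set, nBoot = 10)))

  perm <- sample(9)
  setPerm <- set[perm]
  expect_equal(mrBeta(mrWeightedMode(setPerm, nBoot = 10)),
               mrBeta(mrWeightedMode(set, nBoot = 10)))
  expect_equal(mrBeta(mrWeightedMedian(setPerm, nBoot = 10)),
               mrBeta(mrWeightedMedian(set, nBoot = 10)))
  expect_equal(mrBeta(mrIVW(setPerm)), mrBeta(mrIVW(set)))
})

test_that("weighted median resists up to half the weight being invalid", {
  # 3 of 7 instruments carry large pleiotropy; median stays near truth
  set.seed(301)
  reps <- 60
  medErr <- ivwErr <- numeric(reps)
  for (i in seq_len(reps)) {
    J <- 7
    gamma <- rep(0.2, J)                 # equal instrument strength
    seG <- rep(0.002, J)
    seO <- rep(0.004, J)
    alpha <- c(rep(0.4, 3), rep(0, 4))   # 3/7 of the weight is invalid
    set <- makeInstruments(rnorm(J, gamma, seG), seG,
                           rnorm(J, 0.3 * gamma + alpha, seO), seO)
    medErr[i] <- mrBeta(mrWeightedMedian(set, nBoot = 10)) - 0.3
    ivwErr[i] <- mrBeta(mrIVW(set)) - 0.3
  }
  expect_lt(abs(mean(medErr)), abs(mean(ivwErr)) / 2)
  expect_lt(abs(mean(medErr)), 0.1)
})
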