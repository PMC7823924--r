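test_that("configurations validate their ranges and parse from text", {
  expect_error(simulationConfig("forward", mafRange = c(0, 0.5)),
               "mafRange")
  expect_error(simulationConfig("forward", r2Target = 1.2), "r2Target")
  expect_error(simulationConfig("forward", prevalence = 0), "prevalence")
  expect_error(simulationConfig("forward", pleiotropyMode = "wild"),
               "pleiotropyMode")

  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# demo", "direction: forward", "nExposure: 4000",
               "nOutcome: 4000", "nVariants: 5", "mafRange: 0.2,0.4",
               "r2Target: 0.03", "betaCausal: 0.1", "seed: 9"), f)
  cfg <- readSimulationConfig(f)
  expect_s4_class(cfg, "MRSimConfig")
  expect_equal(cfg@nVariants, 5L)
  expect_equal(cfg@mafRange, c(0.2, 0.4))
  expect_equal(cfg@betaCausal, 0.1)
  writeLines("nonsense line", f)
  expect_error(readSimulationConfig(f), "malformed")
})

test_that("the generator is reproducible and refuses infeasible variance splits", {
  cfg <- simulationConfig("forward", nExposure = 3000, nOutcome = 3000,
                          seed = 4)
  a <- simulateTwoSample(cfg)
  b <- simulateTwoSample(cfg)
  expect_identical(a, b)
  expect_error(
    simulateTwoSample(simulationConfig("forward", nExposure = 1000,
                                       nOutcome = 1000, r2Target = 0.5,
                                       confounderEffects = c(0.8, 0))),
    "infeasible")
})

test_that("realized variance explained and prevalence hit their targets", {
  sim <- simulateTwoSample(simulationConfig("forward", seed = 7))
  expect_gt(sim$truth$realizedR2, 0.022)        # target 0.027 at n = 50,000
  expect_lt(sim$truth$realizedR2, 0.032)
  expect_gt(sim$truth$realizedPrevalence, 0.12) # target 0.13
  expect_lt(sim$truth$realizedPrevalence, 0.14)
})

test_that("summary betas converge to the generative effects", {
  cfg <- simulationConfig("forward", nExposure = 100000, nOutcome = 100000,
                          betaCausal = 0.3, seed = 12)
  sim <- simulateTwoSample(cfg)
  expect_true(all(abs(sim$exposure$beta - sim$truth$gamma) <
                    3 * sim$exposure$se))
  # outcome log-ORs approximate beta * gamma for small effects
  expect_true(all(abs(sim$outcome$beta - 0.3 * sim$truth$gamma) <
                    3 * sim$outcome$se + 0.05 * abs(sim$truth$gamma)))
})

test_that("a single-instrument run flows through the pipeline as a Wald ratio", {
  cfg <- simulationConfig("forward", nExposure = 5000, nOutcome = 5000,
                          nVariants = 1, r2Target = 0.01, betaCausal = 0.2,
                          seed = 3)
  sim <- simulateTwoSample(cfg)
  set <- harmonizeInstruments(sim$exposure, sim$outcome)
  iv <- mrIVW(set)
  wd <- waldRatio(sim$exposure$beta, sim$exposure$se,
                  sim$outcome$beta, sim$outcome$se)
  expect_equal(mrBeta(iv), mrBeta(wd))
  expect_equal(mrSE(iv), mrSE(wd))
})

test_that("pleiotropy regimes honour their constructions", {
  base <- function(mode, ...) {
    cfg <- simulationConfig("forward", nExposure = 2000, nOutcome = 2000,
                            nVariants = 20, pleiotropyMode = mode,
                            seed = 31, ...)
    simulateTwoSample(cfg)$truth
  }
  expect_true(all(base("none")$alpha == 0))
  bal <- base("balanced", pleiotropySD = 0.05)
  expect_equal(mean(bal$alpha), 0, tolerance = 1e-15)
  expect_gt(sd(bal$alpha), 0)
  dir <- base("directional", pleiotropyMean = 0.04, pleiotropySD = 0.01)
  expect_gt(mean(dir$alpha), 0.02)
  crl <- base("correlated", pleiotropySD = 0.05)
  expect_gt(abs(cor(crl$alpha, crl$gamma)), 0.2)
})

test_that("the reverse generator reports a consistent liability-scale estimand", {
  b <- liabilityEffectForPercentChange(-3.26, 0.34)
  cfg <- simulationConfig("reverse", nExposure = 40000, nOutcome = 40000,
                          betaCausal = b, seed = 21)
  sim <- simulateReverseDirection(cfg)
  expect_equal(sim$truth$estimandPercent, -3.26, tolerance = 1e-10)
  expect_equal(sim$truth$realizedPrevalence, 0.34, tolerance = 0.02)
  # exposure-side effects are on the log-odds scale: lambda-scaled gamma
  K <- 0.34
  lambda <- dnorm(qnorm(1 - K)) / (K * (1 - K))
  expect_true(mean(abs(sim$exposure$beta - lambda * sim$truth$gamma) <
                     3.5 * sim$exposure$se) > 0.9)
})

test_that("directional pleiotropy shifts the Egger intercept toward the injected mean", {
  # recovery of the mean direct effect across replicate summary draws;
  # exposure effects are taken as known (the NOME condition Egger assumes)
  set.seed(61)
  reps <- 200
  inter <- numeric(reps)
  for (i in seq_len(reps)) {
    J <- 15
    gamma <- runif(J, 0.05, 0.15)
    seO <- runif(J, 0.005, 0.02)
    alpha <- rnorm(J, 0.01, 0.002)     # InSIDE holds: alpha independent
    set <- makeInstruments(gamma, rep(1e-6, J),
                           rnorm(J, 0.2 * gamma + alpha, seO), seO)
    inter[i] <- mrBeta(mrEgger(set)$intercept)
  }
  mcse <- sd(inter) / sqrt(reps)
  expect_lt(abs(mean(inter) - 0.01), 3 * mcse)
})
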