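# Shared fixture builders (all data generated in code).

# A small well-formed exposure summary table.
toySummary <- function(J = 6, seed = 42, palindromic = FALSE) {
  set.seed(seed)
  pairs <- if (palindromic) matrix(rep(c("A", "T"), J), ncol = 2, byrow = TRUE)
  else matrix(rep(c("A", "G", "T", "C"), length.out = 2 * J), ncol = 2,
              byrow = TRUE)
  data.frame(
    snp = paste0("rs", seq_len(J)),
    ea = pairs[, 1], oa = pairs[, 2],
    eaf = round(runif(J, 0.2, 0.45), 3),
    beta = round(rnorm(J, 0.08, 0.02), 4),
    se = round(runif(J, 0.005, 0.02), 4),
    pval = 1e-8, n = 50000L, stringsAsFactors = FALSE
  )
}

# Matching outcome table: Gamma = slope * gamma + noise.
toyOutcome <- function(exposure, slope = 0, noiseSd = 0, seed = 43) {
  set.seed(seed)
  out <- exposure
  out$beta <- slope * exposure$beta + rnorm(nrow(exposure), 0, noiseSd)
  out$se <- round(runif(nrow(exposure), 0.01, 0.03), 4)
  out$pval <- 0.5
  out
}

# Random instrument set for algebraic-identity checks.
randomInstrumentSet <- function(J, seed) {
  set.seed(seed)
  makeInstruments(
    gamma = rnorm(J, 0, 0.2) + sign(rnorm(J)) * 0.05,
    seGamma = runif(J, 0.005, 0.05),
    Gamma = rnorm(J, 0, 0.1),
    seGammaOut = runif(J, 0.01, 0.1)
  )
}

# Summary-level two-sample draw under the forward study conditions
# (J strong instruments explaining r2 of a unit-variance exposure,
# binary outcome with case fraction K), with optional directional
# pleiotropy spike on the first variant expressed in outcome-SE units.
summaryLevelDraw <- function(J = 6, n = 50000, r2 = 0.027, K = 0.13,
                             beta = 0.2, spikeSE = 0, mafRange = c(0.18, 0.5)) {
  f <- runif(J, mafRange[1], mafRange[2])
  raw <- runif(J, 0.5, 1.5) * sample(c(-1, 1), J, replace = TRUE)
  vg <- 2 * f * (1 - f)
  gamma <- raw * sqrt(r2 / sum(raw^2 * vg))
  seG <- 1 / sqrt(n * vg)
  seO <- 1 / sqrt(n * K * (1 - K) * vg)
  alpha <- c(spikeSE * seO[1], rep(0, J - 1))
  makeInstruments(
    gamma = rnorm(J, gamma, seG), seGamma = seG,
    Gamma = rnorm(J, beta * gamma + alpha, seO), seGammaOut = seO
  )
}
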