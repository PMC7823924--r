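#' Build a simulation configuration
#'
#' Direction-specific defaults emulate the statistical structure of the
#' motivating study's data sources. Forward (continuous 25(OH)D exposure,
#' binary depression outcome): 6 strong instruments with MAF at least
#' 0.18 jointly explaining 2.7% of the log-exposure variance, outcome
#' prevalence 13%, two samples of 50,000 (a desk-scale stand-in for the
#' consortium and biobank samples). Reverse (binary depression liability
#' exposure, continuous log-25(OH)D outcome): 44 weak instruments with
#' MAF at least 0.07 explaining 0.2% of liability variance, exposure-GWAS
#' case fraction 0.34 (the case-enriched composition of a case-control
#' depression GWAS with 113,154 cases and 218,523 controls), samples of
#' 330,000 and 300,000.
#'
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param nExposure,nOutcome sample sizes of the two disjoint samples.
#' @param nVariants number of independent instruments J.
#' @param mafRange allele-frequency range, within (0, 0.5].
#' @param r2Target variance fraction explained by instruments jointly.
#' @param betaCausal causal effect (log-odds per unit exposure forward;
#'   outcome log units per unit liability reverse).
#' @param prevalence case fraction of the binary trait.
#' @param confounderEffects length-2: effect of the standard-normal
#'   confounder U on exposure/liability and on the outcome link scale.
#' @param pleiotropyMode \code{"none"}, \code{"balanced"},
#'   \code{"directional"} or \code{"correlated"} (the last violates the
#'   InSIDE assumption by construction).
#' @param pleiotropyMean,pleiotropySD mean and SD of the direct
#'   variant-outcome effects alpha.
#' @param seed integer seed.
#' @return an [MRSimConfig-class] object.
#' @export
simulationConfig <- function(direction = c("forward", "reverse"),
                             nExposure = NULL, nOutcome = NULL,
                             nVariants = NULL, mafRange = NULL,
                             r2Target = NULL, betaCausal = 0,
                             prevalence = NULL,
                             confounderEffects = c(0, 0),
                             pleiotropyMode = "none", pleiotropyMean = 0,
                             pleiotropySD = 0, seed = 1) {
  direction <- match.arg(direction)
  d <- if (direction == "forward")
    list(nExposure = 50000L, nOutcome = 50000L, nVariants = 6L,
         mafRange = c(0.18, 0.5), r2Target = 0.027, prevalence = 0.13)
  else
    list(nExposure = 330000L, nOutcome = 300000L, nVariants = 44L,
         mafRange = c(0.07, 0.5), r2Target = 0.002, prevalence = 0.34)
  pick <- function(x, default) if (is.null(x)) default else x
  new("MRSimConfig",
      direction = direction,
      nExposure = as.integer(pick(nExposure, d$nExposure)),
      nOutcome = as.integer(pick(nOutcome, d$nOutcome)),
      nVariants = as.integer(pick(nVariants, d$nVariants)),
      mafRange = pick(mafRange, d$mafRange),
      r2Target = pick(r2Target, d$r2Target),
      betaCausal = betaCausal,
      prevalence = pick(prevalence, d$prevalence),
      confounderEffects = confounderEffects,
      pleiotropyMode = pleiotropyMode,
      pleiotropyMean = pleiotropyMean, pleiotropySD = pleiotropySD,
      seed = as.integer(seed))
}

#' Read a simulation configuration from a key: value text file
#'
#' One \code{key: value} pair per line; keys mirror the arguments of
#' [simulationConfig()]; pairs such as \code{mafRange} are comma-separated;
#' lines starting with \code{#} are ignored.
#'
#' @param path path to the text file.
#' @return an [MRSimConfig-class] object.
#' @export
readSimulationConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"),
                        character(1)))
  args <- list()
  numPair <- c("mafRange", "confounderEffects")
  numScalar <- c("nExposure", "nOutcome", "nVariants", "r2Target",
                 "betaCausal", "prevalence", "pleiotropyMean",
                 "pleiotropySD", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% numPair) args[[k]] <- as.numeric(strsplit(v, ",")[[1]])
    else if (k %in% numScalar) args[[k]] <- as.numeric(v)
    else if (k %in% c("direction", "pleiotropyMode")) args[[k]] <- v
    else stop("unknown config key: ", k)
  }
  do.call(simulationConfig, args)
}

# Draw per-variant allele frequencies and effect sizes: magnitudes uniform
# in [0.5, 1.5] with random signs, rescaled so the instruments explain
# exactly r2Target of unit exposure/liability variance in expectation.
drawVariantEffects <- function(config) {
  J <- config@nVariants
  f <- runif(J, config@mafRange[1], config@mafRange[2])
  raw <- runif(J, 0.5, 1.5) * sample(c(-1, 1), J, replace = TRUE)
  vg <- 2 * f * (1 - f)
  scale <- if (config@r2Target > 0)
    sqrt(config@r2Target / sum(raw^2 * vg)) else 0
  list(maf = f, gamma = raw * scale)
}

drawAlpha <- function(config, gamma) {
  J <- config@nVariants
  m <- config@pleiotropyMean; s <- config@pleiotropySD
  switch(config@pleiotropyMode,
    none = rep(0, J),
    balanced = { a <- s * rnorm(J); a - mean(a) },
    directional = m + s * rnorm(J),
    correlated = {
      gs <- (gamma - mean(gamma)) / max(sd(gamma), .Machine$double.eps)
      m + s * (0.7 * gs + sqrt(1 - 0.49) * rnorm(J))
    })
}

allelePairs <- function(J) {
  pool <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C", "G", "A", "C", "T"),
                 ncol = 2, byrow = TRUE)
  idx <- rep_len(seq_len(nrow(pool)), J)
  pool[idx, , drop = FALSE]
}

drawGenotypes <- function(n, maf) {
  matrix(rbinom(n * length(maf), 2L, rep(maf, each = n)), nrow = n)
}

summaryFromScan <- function(snps, alleles, G, scan, n) {
  data.frame(
    snp = snps, ea = alleles[, 1], oa = alleles[, 2],
    eaf = colMeans(G) / 2, beta = scan$beta, se = scan$se,
    pval = scan$pval, n = n, stringsAsFactors = FALSE
  )
}

# Multiple-regression R2 of y on all genotype columns (normal equations).
jointR2 <- function(G, y) {
  Gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  b <- solve(crossprod(Gc), crossprod(Gc, yc))
  drop(crossprod(yc, Gc %*% b)) / sum(yc^2)
}

solveIntercept <- function(eta, K) {
  uniroot(function(b0) mean(plogis(b0 + eta)) - K,
          lower = -30, upper = 30, tol = 1e-8)$root
}

checkNoiseVariance <- function(v, what, bound) {
  if (v <= 0)
    stop("infeasible configuration: ", what,
         " leaves non-positive residual variance (requires ", bound, ")")
  v
}

#' Simulate a two-sample GWAS (forward direction)
#'
#' Generates two disjoint samples. In the exposure sample, genotypes are
#' drawn as binomial(2, f) per variant and the continuous (natural-log
#' scale) exposure is \eqn{X = \sum_j \gamma_j G_j + c_x U + \epsilon},
#' scaled to unit variance with the instruments explaining
#' \code{r2Target} of it; per-variant summaries come from single-variant
#' linear regression. In the outcome sample, the binary outcome follows
#' \eqn{logit P = \beta_0 + \beta X + \sum_j \alpha_j G_j + c_y U} with
#' \eqn{\beta_0} solved numerically so the case fraction matches the
#' configured prevalence; per-variant summaries come from single-variant
#' logistic score regression (log-OR scale). The two samples share no
#' individuals, and the run is reproducible from the seed.
#'
#' @param config an [MRSimConfig-class] with \code{direction "forward"}.
#' @return list with \code{exposure} and \code{outcome} summary tables in
#'   the canonical dialect and \code{truth} (list: betaCausal, gamma,
#'   alpha, maf, confounderEffects, realizedR2, realizedPrevalence,
#'   interceptOutcome).
#' @export
simulateTwoSample <- function(config) {
  stopifnot(is(config, "MRSimConfig"))
  if (config@direction != "forward")
    stop("config direction must be 'forward'; see simulateReverseDirection()")
  cx <- config@confounderEffects[1]; cy <- config@confounderEffects[2]
  withSeed(config@seed, {
    eff <- drawVariantEffects(config)
    alpha <- drawAlpha(config, eff$gamma)
    varNoise <- checkNoiseVariance(
      1 - config@r2Target - cx^2,
      "r2Target plus squared exposure confounding",
      "r2Target + confounderEffects[1]^2 < 1")
    snps <- paste0("snp", seq_len(config@nVariants))
    alleles <- allelePairs(config@nVariants)

    # exposure sample
    mu <- sum(2 * eff$maf * eff$gamma)  # centre the genetic score
    Gx <- drawGenotypes(config@nExposure, eff$maf)
    Ux <- rnorm(config@nExposure)
    X <- drop(Gx %*% eff$gamma) - mu + cx * Ux +
      rnorm(config@nExposure, sd = sqrt(varNoise))
    expTab <- summaryFromScan(snps, alleles, Gx, fastLinearScan(Gx, X),
                              config@nExposure)
    realizedR2 <- jointR2(Gx, X)

    # outcome sample (disjoint individuals)
    Gy <- drawGenotypes(config@nOutcome, eff$maf)
    Uy <- rnorm(config@nOutcome)
    Xy <- drop(Gy %*% eff$gamma) - mu + cx * Uy +
      rnorm(config@nOutcome, sd = sqrt(varNoise))
    eta <- config@betaCausal * Xy + drop(Gy %*% alpha) + cy * Uy
    b0 <- solveIntercept(eta, config@prevalence)
    y <- rbinom(config@nOutcome, 1L, plogis(b0 + eta))
    outTab <- summaryFromScan(snps, alleles, Gy, fastLogisticScan(Gy, y),
                              config@nOutcome)

    list(exposure = expTab, outcome = outTab,
         truth = list(betaCausal = config@betaCausal, gamma = eff$gamma,
                      alpha = alpha, maf = eff$maf,
                      confounderEffects = config@confounderEffects,
                      realizedR2 = realizedR2,
                      realizedPrevalence = mean(y),
                      interceptOutcome = b0))
  })
}

#' Liability-scale effect giving a target percent change
#'
#' In the reverse direction the instruments act on depression liability
#' but their exposure-side summary effects are reported as log odds
#' ratios. For small per-variant effects the log-OR is the liability
#' effect multiplied by \eqn{\lambda = \phi(t) / (K(1-K))} with
#' \eqn{t = \Phi^{-1}(1-K)}, so a causal effect of \code{betaCausal}
#' outcome log-units per unit liability is estimated by MR as
#' \code{betaCausal / lambda} per unit log-odds. This helper inverts that:
#' it returns the \code{betaCausal} whose MR estimand, after the
#' percent-change transform, equals \code{percent}.
#'
#' @param percent target percent change in the outcome per unit log-odds
#'   of the exposure (e.g. -3.26).
#' @param caseFraction case fraction K of the exposure sample.
#' @return liability-scale causal effect.
#' @export
liabilityEffectForPercentChange <- function(percent, caseFraction) {
  stopifnot(percent > -100, caseFraction > 0, caseFraction < 1)
  t <- qnorm(1 - caseFraction)
  lambda <- dnorm(t) / (caseFraction * (1 - caseFraction))
  log(1 + percent / 100) * lambda
}

#' Simulate a two-sample GWAS (reverse direction)
#'
#' Depression as exposure under a liability-threshold model: liability
#' \eqn{L = \sum_j \gamma_j G_j + c_x U + \epsilon} (unit variance,
#' instruments explaining \code{r2Target}); cases are individuals above
#' the \eqn{1 - K} liability quantile. Variant-exposure summaries are
#' single-variant logistic score regressions of case status (log-OR
#' scale). In the disjoint outcome sample the continuous log-scale outcome
#' is \eqn{Y = \beta L + c_y U + \epsilon_y}, scaled to unit variance;
#' variant-outcome summaries are single-variant linear regressions.
#'
#' @param config an [MRSimConfig-class] with \code{direction "reverse"}.
#' @return list as for [simulateTwoSample()]; \code{truth} additionally
#'   carries \code{estimandLogScale} (the IVW estimand per unit log-odds)
#'   and \code{estimandPercent} (its percent-change transform).
#' @export
simulateReverseDirection <- function(config) {
  stopifnot(is(config, "MRSimConfig"))
  if (config@direction != "reverse")
    stop("config direction must be 'reverse'; see simulateTwoSample()")
  cx <- config@confounderEffects[1]; cy <- config@confounderEffects[2]
  b <- config@betaCausal
  withSeed(config@seed, {
    eff <- drawVariantEffects(config)
    alpha <- drawAlpha(config, eff$gamma)
    varNoise <- checkNoiseVariance(
      1 - config@r2Target - cx^2,
      "r2Target plus squared liability confounding",
      "r2Target + confounderEffects[1]^2 < 1")
    # Y has unit total variance: var(bL + cy U + eps) with cov(L, U) = cx.
    varNoiseY <- checkNoiseVariance(
      1 - b^2 - cy^2 - 2 * b * cx * cy,
      "betaCausal plus outcome confounding",
      "betaCausal^2 + confounderEffects[2]^2 + 2*betaCausal*prod(confounderEffects) < 1")
    snps <- paste0("snp", seq_len(config@nVariants))
    alleles <- allelePairs(config@nVariants)
    thr <- qnorm(1 - config@prevalence)

    # exposure sample: binary depression from thresholded liability
    mu <- sum(2 * eff$maf * eff$gamma)  # centre the genetic score
    Gx <- drawGenotypes(config@nExposure, eff$maf)
    Lx <- drop(Gx %*% eff$gamma) - mu + cx * rnorm(config@nExposure) +
      rnorm(config@nExposure, sd = sqrt(varNoise))
    D <- as.integer(Lx > thr)
    expTab <- summaryFromScan(snps, alleles, Gx, fastLogisticScan(Gx, D),
                              config@nExposure)
    realizedR2 <- jointR2(Gx, Lx)

    # outcome sample: continuous log-scale outcome
    Gy <- drawGenotypes(config@nOutcome, eff$maf)
    Uy <- rnorm(config@nOutcome)
    Ly <- drop(Gy %*% eff$gamma) - mu + cx * Uy +
      rnorm(config@nOutcome, sd = sqrt(varNoise))
    Y <- b * Ly + drop(Gy %*% alpha) + cy * Uy +
      rnorm(config@nOutcome, sd = sqrt(varNoiseY))
    outTab <- summaryFromScan(snps, alleles, Gy, fastLinearScan(Gy, Y),
                              config@nOutcome)

    K <- config@prevalence
    lambda <- dnorm(thr) / (K * (1 - K))
    estimand <- b / lambda
    list(exposure = expTab, outcome = outTab,
         truth = list(betaCausal = b, gamma = eff$gamma, alpha = alpha,
                      maf = eff$maf,
                      confounderEffects = config@confounderEffects,
                      realizedR2 = realizedR2,
                      realizedPrevalence = mean(D),
                      estimandLogScale = estimand,
                      estimandPercent = 100 * (exp(estimand) - 1)))
  })
}

#' Simulate an individual-level observational cohort
#'
#' Per-individual table emulating a biobank cross-section: natural-log
#' serum 25(OH)D (normal around log 49 nmol/L, shifted by covariates),
#' binary depression from a logistic model in the covariates and
#' log-25(OH)D, and nested covariate tiers: basic (age group, sex),
#' socioeconomic (+ a socioeconomic score), lifestyle (+ a lifestyle
#' score, from which descriptive BMI and physical-activity categories are
#' derived).
#'
#' @param n cohort size.
#' @param orPer50 true odds ratio of depression per 50% higher 25(OH)D
#'   (1 = no effect).
#' @param prevalence depression prevalence (default 0.13).
#' @param confounding scalar multiplying the default covariate effects on
#'   both exposure and outcome (0 = none, 1 = moderate confounding in
#'   which lifestyle raises 25(OH)D and lowers depression risk).
#' @param sdLogExposure total SD of log 25(OH)D (default 0.45).
#' @param seed integer seed.
#' @return data.frame with columns \code{ln_25ohd}, \code{vitd_nmol},
#'   \code{depression}, \code{ageGroup}, \code{sex}, \code{sesScore},
#'   \code{lifestyleScore}, \code{bmiCategory}, \code{activity}.
#' @export
simulateObservationalCohort <- function(n = 20000, orPer50 = 1,
                                        prevalence = 0.13,
                                        confounding = 0,
                                        sdLogExposure = 0.45, seed = 1) {
  stopifnot(n >= 10, orPer50 > 0, prevalence > 0, prevalence < 1,
            confounding >= 0, sdLogExposure > 0)
  withSeed(seed, {
    ageNum <- sample(0:2, n, replace = TRUE, prob = c(0.22, 0.32, 0.46))
    sex <- rbinom(n, 1L, 0.492)          # 1 = female
    ses <- rnorm(n)
    lifestyle <- rnorm(n)
    # covariate effects on log-exposure (log units) and outcome (log-odds)
    ex <- confounding * c(age = 0.04, ses = 0.03, lifestyle = 0.10)
    oy <- confounding * c(age = -0.15, ses = -0.10, lifestyle = -0.40)
    shift <- ex["age"] * (ageNum - 1) + ex["ses"] * ses +
      ex["lifestyle"] * lifestyle
    varShift <- var(shift)
    if (varShift >= sdLogExposure^2)
      stop("infeasible configuration: covariate effects exceed the total ",
           "log-exposure variance")
    ln25 <- log(49) + shift +
      rnorm(n, sd = sqrt(sdLogExposure^2 - varShift))
    bExp <- log(orPer50) / log(1.5)
    eta <- bExp * ln25 + 0.35 * sex + oy["age"] * (ageNum - 1) +
      oy["ses"] * ses + oy["lifestyle"] * lifestyle
    b0 <- solveIntercept(eta, prevalence)
    depression <- rbinom(n, 1L, plogis(b0 + eta))
    bmi <- cut(-0.8 * lifestyle + rnorm(n, sd = 0.6),
               breaks = c(-Inf, -1.5, 0, 1, Inf),
               labels = c("underweight", "normal", "overweight", "obese"))
    act <- cut(lifestyle + rnorm(n, sd = 0.6),
               breaks = c(-Inf, -1.6, 1.2, Inf),
               labels = c("none", "light_moderate", "strenuous"))
    data.frame(
      ln_25ohd = ln25, vitd_nmol = exp(ln25),
      depression = depression,
      ageGroup = factor(c("39-49", "50-59", "60-73")[ageNum + 1],
                        levels = c("39-49", "50-59", "60-73")),
      sex = factor(ifelse(sex == 1, "female", "male"),
                   levels = c("male", "female")),
      sesScore = ses, lifestyleScore = lifestyle,
      bmiCategory = bmi, activity = act,
      stringsAsFactors = FALSE
    )
  })
}
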