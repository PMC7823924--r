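# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded estimators do not perturb user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

newEstimate <- function(method, beta, se, J, qStat = NA_real_,
                        overdispersion = 1) {
  z <- qnorm(0.975)
  new("MREstimate",
      method = method, beta = beta, se = se,
      ciLower = beta - z * se, ciUpper = beta + z * se,
      pvalue = 2 * pnorm(-abs(beta / se)),
      nInstruments = as.integer(J), qStat = qStat,
      overdispersion = overdispersion)
}

# Half-up decimal rounding (R's round() is half-even); tiny epsilon guards
# against binary representation of exact .5 ratios.
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Per-variant simple linear regression of y on each column of G.
# Returns beta, se (residual-based), and two-sided normal p.
fastLinearScan <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  ybar <- mean(y)
  sxx <- colSums(G * G) - n * gbar^2
  sxy <- as.vector(crossprod(G, y)) - n * gbar * ybar
  syy <- sum(y^2) - n * ybar^2
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  z <- beta / se
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(z)))
}

# Per-variant logistic score regression of binary y on each column of G:
# the one-step estimator U/I with score information I evaluated under the
# intercept-only null, reported on the log-odds scale.
fastLogisticScan <- function(G, y) {
  n <- length(y)
  ybar <- mean(y)
  gbar <- colMeans(G)
  sxx <- colSums(G * G) - n * gbar^2
  U <- as.vector(crossprod(G, y - ybar))
  info <- ybar * (1 - ybar) * sxx
  beta <- U / info
  se <- 1 / sqrt(info)
  z <- beta / se
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(z)))
}

# Closed-form IVW slope for internal reuse (no object construction).
ivwSlope <- function(gamma, Gamma, seOutcome) {
  w <- 1 / seOutcome^2
  sum(w * gamma * Gamma) / sum(w * gamma^2)
}
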