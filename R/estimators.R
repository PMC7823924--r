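#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate: the variant-outcome effect divided by
#' the variant-exposure effect, with the first-order delta-method standard
#' error \eqn{\sigma_\Gamma / |\gamma|}.
#'
#' @param gamma variant-exposure effect (must be non-zero).
#' @param seGamma its standard error (recorded, not used in the first-order
#'   SE).
#' @param Gamma variant-outcome effect.
#' @param seGammaOut its standard error.
#' @return an [MREstimate-class] with method \code{"wald"}.
#' @examples
#' waldRatio(0.5, 0.05, 0.1, 0.02)  # beta 0.2, se 0.04
#' @export
waldRatio <- function(gamma, seGamma, Gamma, seGammaOut) {
  if (!is.finite(gamma) || gamma == 0)
    stop("Wald ratio undefined: variant-exposure effect is zero")
  beta <- Gamma / gamma
  se <- seGammaOut / abs(gamma)
  newEstimate("wald", beta, se, 1L)
}

#' Inverse-variance-weighted estimator
#'
#' The primary two-sample MR estimator: the slope of the zero-intercept
#' weighted regression of outcome effects on exposure effects with weights
#' \eqn{w_j = \sigma_{\Gamma j}^{-2}}, algebraically identical to the
#' fixed-effect inverse-variance meta-analysis of the per-variant Wald
#' ratios. Under the multiplicative random-effects model (the default) the
#' fixed-effect SE is scaled by \eqn{\max(1, \sqrt{Q/(J-1)})}, so
#' heterogeneity can widen but never shrink the interval.
#'
#' @param object an [MRInstruments-class] object.
#' @param effectsModel \code{"multiplicative"} (default) or \code{"fixed"}.
#' @return an [MREstimate-class] with method \code{"ivw"}.
#' @export
mrIVW <- function(object, effectsModel = c("multiplicative", "fixed")) {
  stopifnot(is(object, "MRInstruments"))
  effectsModel <- match.arg(effectsModel)
  g <- exposureBeta(object); G <- outcomeBeta(object)
  sG <- outcomeSE(object)
  J <- length(g)
  w <- 1 / sG^2
  denom <- sum(w * g^2)
  beta <- sum(w * g * G) / denom
  seFixed <- 1 / sqrt(denom)
  Q <- sum(w * (G - beta * g)^2)
  od <- if (effectsModel == "multiplicative" && J >= 2)
    max(1, sqrt(Q / (J - 1))) else 1
  newEstimate("ivw", beta, seFixed * od, J, qStat = Q, overdispersion = od)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, after orienting every instrument so that the
#' exposure effect is non-negative (Egger regression is not invariant to
#' allele orientation; this convention is declared explicitly). The slope
#' is the pleiotropy-adjusted causal estimate; the intercept estimates the
#' average directional pleiotropic effect, and its p-value is the
#' directional-pleiotropy test. Standard errors carry the multiplicative
#' overdispersion factor \eqn{\max(1, \sqrt{RSS_w/(J-2)})}.
#'
#' With \code{fitIntercept = FALSE} the intercept is constrained to zero,
#' which reproduces the IVW estimator exactly (nested-model identity); the
#' overdispersion denominator is then \eqn{J-1}.
#'
#' @param object an [MRInstruments-class] object with at least 3
#'   instruments (2 when \code{fitIntercept = FALSE}).
#' @param fitIntercept logical; fit the pleiotropy intercept (default TRUE).
#' @return list with elements \code{slope} and (when fitted)
#'   \code{intercept}, both [MREstimate-class] objects.
#' @export
mrEgger <- function(object, fitIntercept = TRUE) {
  stopifnot(is(object, "MRInstruments"))
  g <- exposureBeta(object); G <- outcomeBeta(object)
  sG <- outcomeSE(object)
  J <- length(g)
  flip <- g < 0
  g <- abs(g); G <- ifelse(flip, -G, G)
  w <- 1 / sG^2
  if (!fitIntercept) {
    if (J < 2) stop("at least 2 instruments required")
    denom <- sum(w * g^2)
    beta <- sum(w * g * G) / denom
    rss <- sum(w * (G - beta * g)^2)
    od <- max(1, sqrt(rss / (J - 1)))
    return(list(slope = newEstimate("egger_slope", beta, od / sqrt(denom),
                                    J, qStat = rss, overdispersion = od)))
  }
  if (J < 3) stop("MR-Egger requires at least 3 instruments")
  sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g^2)
  det <- sw * swgg - swg^2
  if (det <= .Machine$double.eps * sw * swgg)
    stop("exposure effects are collinear after orientation; Egger slope undefined")
  swy <- sum(w * G); swgy <- sum(w * g * G)
  slope <- (sw * swgy - swg * swy) / det
  inter <- (swgg * swy - swg * swgy) / det
  resid <- G - inter - slope * g
  rss <- sum(w * resid^2)
  od <- max(1, sqrt(rss / (J - 2)))
  seSlope <- od * sqrt(sw / det)
  seInter <- od * sqrt(swgg / det)
  list(
    slope = newEstimate("egger_slope", slope, seSlope, J,
                        qStat = rss, overdispersion = od),
    intercept = newEstimate("egger_intercept", inter, seInter, J,
                            qStat = rss, overdispersion = od)
  )
}

# Weighted median of ratio estimates via cumulative-midpoint interpolation.
weightedMedianPoint <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  p <- weights[o] / sum(weights)
  S <- cumsum(p) - p / 2
  if (0.5 <= S[1]) return(b[1])
  if (0.5 >= S[length(S)]) return(b[length(S)])
  approx(S, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when at least half of the weight comes from valid
#' instruments. Per-variant Wald ratios are ordered and the inverse
#' -variance-weighted median is read off by linear interpolation of the
#' cumulative weight midpoints at 0.5. The standard error comes from a
#' seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on their estimates with their reported
#' SEs and the estimator is recomputed.
#'
#' @param object an [MRInstruments-class] object with at least 2
#'   instruments.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (default 1).
#' @return an [MREstimate-class] with method \code{"weighted_median"}.
#' @export
mrWeightedMedian <- function(object, nBoot = 1000, seed = 1) {
  stopifnot(is(object, "MRInstruments"))
  g <- exposureBeta(object); sg <- exposureSE(object)
  G <- outcomeBeta(object); sG <- outcomeSE(object)
  J <- length(g)
  if (J < 2) stop("weighted median requires at least 2 instruments")
  est <- weightedMedianPoint(G / g, g^2 / sG^2)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      gs <- rnorm(J, g, sg)
      Gs <- rnorm(J, G, sG)
      weightedMedianPoint(Gs / gs, gs^2 / sG^2)
    }, numeric(1))
  })
  se <- sd(boots)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  newEstimate("weighted_median", est, se, J)
}

# Weighted-mode point estimate: argmax of a weighted normal-kernel density
# on a fixed 512-point grid spanning the ratios +/- 3 bandwidths.
weightedModePoint <- function(ratios, weights, phi = 1) {
  ratios <- unname(ratios)
  p <- weights / sum(weights)
  s <- 0.9 * min(sd(ratios), mad(ratios)) * length(ratios)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(ratios[1])
  h <- phi * s
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(p * dnorm(x, ratios, h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Consistent when the largest group of instruments sharing the same ratio
#' is valid (zero modal pleiotropy). Per-variant ratios are smoothed with a
#' weighted normal kernel whose bandwidth is
#' \eqn{\phi \cdot 0.9 \min(sd, mad) J^{-1/5}} (mad with the usual 1.4826
#' normal-consistency constant) and the estimate is the density argmax on a
#' fixed 512-point grid, which makes the estimate bit-reproducible.
#' Standard error by seeded parametric bootstrap as for the weighted
#' median. When all ratios coincide the common value is returned directly.
#'
#' @param object an [MRInstruments-class] object with at least 3
#'   instruments.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (default 1).
#' @return an [MREstimate-class] with method \code{"weighted_mode"}.
#' @export
mrWeightedMode <- function(object, phi = 1, nBoot = 1000, seed = 1) {
  stopifnot(is(object, "MRInstruments"), phi > 0)
  g <- exposureBeta(object); sg <- exposureSE(object)
  G <- outcomeBeta(object); sG <- outcomeSE(object)
  J <- length(g)
  if (J < 3) stop("weighted mode requires at least 3 instruments")
  est <- weightedModePoint(G / g, g^2 / sG^2, phi)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      gs <- rnorm(J, g, sg)
      Gs <- rnorm(J, G, sG)
      weightedModePoint(Gs / gs, gs^2 / sG^2, phi)
    }, numeric(1))
  })
  se <- sd(boots)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  newEstimate("weighted_mode", est, se, J)
}

#' Run a battery of MR estimators
#'
#' Convenience wrapper running any of \code{ivw}, \code{egger},
#' \code{median}, \code{mode} on one instrument set and returning a tidy
#' table (Egger contributes slope and intercept rows).
#'
#' @param object an [MRInstruments-class] object.
#' @param methods character subset of
#'   \code{c("ivw", "egger", "median", "mode")}.
#' @param nBoot bootstrap replicates for median/mode.
#' @param seed bootstrap seed.
#' @param effectsModel IVW effects model.
#' @return data.frame with one row per estimate.
#' @export
mrEstimateAll <- function(object,
                          methods = c("ivw", "egger", "median", "mode"),
                          nBoot = 1000, seed = 1,
                          effectsModel = "multiplicative") {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("ivw" %in% methods)
    out$ivw <- estimateAsData(mrIVW(object, effectsModel))
  if ("egger" %in% methods) {
    e <- mrEgger(object)
    out$egger <- rbind(estimateAsData(e$slope), estimateAsData(e$intercept))
  }
  if ("median" %in% methods)
    out$median <- estimateAsData(mrWeightedMedian(object, nBoot, seed))
  if ("mode" %in% methods)
    out$mode <- estimateAsData(mrWeightedMode(object, 1, nBoot, seed))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
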