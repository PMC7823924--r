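# Leave-one-out IVW slopes for every j, computed from full sums.
looSlopes <- function(g, G, w) {
  s1 <- sum(w * g * G); s2 <- sum(w * g^2)
  (s1 - w * g * G) / (s2 - w * g^2)
}

#' MR-PRESSO: global, outlier and distortion tests
#'
#' Resampling-based detection of horizontal pleiotropy on summary data.
#' For each variant j the expected outcome effect is the leave-one-out IVW
#' prediction \eqn{\beta_{(-j)} \gamma_j}; the observed residual sum of
#' squares (inverse-variance weighted) is compared with its Monte-Carlo
#' null distribution obtained by redrawing \eqn{\Gamma_j^* \sim
#' N(\beta_{(-j)}\gamma_j, \sigma_{\Gamma j}^2)} and \eqn{\gamma_j^* \sim
#' N(\gamma_j, \sigma_{\gamma j}^2)} and recomputing the statistic (global
#' test). Per-variant squared residuals are compared with their simulated
#' counterparts, Bonferroni-adjusted by J (outlier test). When outliers
#' are flagged, the percent change of the IVW estimate after their removal
#' is compared with the changes produced by removing random subsets of the
#' same size (distortion test). All Monte-Carlo p-values use the add-one
#' convention and are therefore never exactly zero.
#'
#' @param object an [MRInstruments-class] object with at least 4
#'   instruments.
#' @param nSim Monte-Carlo replicates (default 1000; values below 100 are
#'   refused as the p-value resolution becomes too coarse).
#' @param seed integer seed (default 1).
#' @param outlierAlpha threshold on the Bonferroni-adjusted per-variant
#'   p-value (default 0.05).
#' @return an [MRPressoResult-class] object.
#' @export
mrPresso <- function(object, nSim = 1000, seed = 1, outlierAlpha = 0.05) {
  stopifnot(is(object, "MRInstruments"))
  g <- exposureBeta(object); sg <- exposureSE(object)
  G <- outcomeBeta(object); sG <- outcomeSE(object)
  J <- length(g)
  if (J < 4)
    stop("MR-PRESSO requires at least 4 instruments (leave-one-out IVW needs >= 3)")
  if (nSim < 100)
    stop("nSim < 100 gives too coarse a Monte-Carlo p-value resolution")
  snps <- variantIds(object)
  w <- 1 / sG^2

  bLoo <- looSlopes(g, G, w)
  resObs <- G - bLoo * g
  rssObs <- sum(w * resObs^2)

  sim <- withSeed(seed, {
    rssStar <- numeric(nSim)
    exceed <- numeric(J)
    for (i in seq_len(nSim)) {
      gs <- rnorm(J, g, sg)
      Gs <- rnorm(J, bLoo * g, sG)
      bs <- looSlopes(gs, Gs, w)
      rs <- Gs - bs * gs
      rssStar[i] <- sum(w * rs^2)
      exceed <- exceed + (rs^2 >= resObs^2)
    }
    list(rssStar = rssStar, exceed = exceed)
  })
  globalP <- (1 + sum(sim$rssStar >= rssObs)) / (nSim + 1)
  pRaw <- (1 + sim$exceed) / (nSim + 1)
  pAdj <- pmin(pRaw * J, 1)
  names(pAdj) <- snps
  outliers <- snps[pAdj <= outlierAlpha]

  betaRaw <- mrIVW(object)
  betaCorrected <- NULL
  distortionCoef <- NA_real_
  distortionP <- NA_real_
  if (length(outliers) && (J - length(outliers)) >= 2) {
    keep <- setdiff(snps, outliers)
    betaCorrected <- mrIVW(object[keep])
    bR <- mrBeta(betaRaw); bC <- mrBeta(betaCorrected)
    distortionCoef <- 100 * (bR - bC) / abs(bC)
    k <- length(outliers)
    coefStar <- withSeed(seed + 1L, {
      vapply(seq_len(nSim), function(i) {
        idx <- sample.int(J, J - k)
        bS <- ivwSlope(g[idx], G[idx], sG[idx])
        100 * (bR - bS) / abs(bS)
      }, numeric(1))
    })
    distortionP <- (1 + sum(abs(coefStar) >= abs(distortionCoef))) / (nSim + 1)
  } else if (length(outliers)) {
    warning("outliers flagged but fewer than 2 instruments would remain; ",
            "corrected estimate not computed")
  }
  new("MRPressoResult",
      rssObserved = rssObs, globalP = globalP, perVariantP = pAdj,
      outliers = outliers, betaRaw = betaRaw,
      betaCorrected = betaCorrected, distortionCoef = distortionCoef,
      distortionP = distortionP, nSim = as.integer(nSim),
      seed = as.integer(seed))
}
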