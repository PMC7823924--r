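#' @describeIn MRInstruments-class variant identifiers of retained
#'   instruments.
#' @export
setMethod("variantIds", "MRInstruments", function(x) x@data$snp)

#' @describeIn MRInstruments-class number of retained instruments J.
#' @export
setMethod("nInstruments", "MRInstruments", function(x) nrow(x@data))

#' @describeIn MRInstruments-class data.frame of dropped variants and
#'   drop reasons.
#' @export
setMethod("droppedVariants", "MRInstruments", function(x) x@dropped)

#' @describeIn MRInstruments-class variant-exposure effects gamma.
#' @export
setMethod("exposureBeta", "MRInstruments",
          function(x) setNames(x@data$betaExposure, x@data$snp))

#' @describeIn MRInstruments-class standard errors of gamma.
#' @export
setMethod("exposureSE", "MRInstruments",
          function(x) setNames(x@data$seExposure, x@data$snp))

#' @describeIn MRInstruments-class variant-outcome effects Gamma.
#' @export
setMethod("outcomeBeta", "MRInstruments",
          function(x) setNames(x@data$betaOutcome, x@data$snp))

#' @describeIn MRInstruments-class standard errors of Gamma.
#' @export
setMethod("outcomeSE", "MRInstruments",
          function(x) setNames(x@data$seOutcome, x@data$snp))

#' @describeIn MRInstruments-class subset an instrument set by index,
#'   logical mask or variant id.
#' @param i index, logical vector or character vector of variant ids.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "MRInstruments", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@data$snp)
  if (anyNA(i)) stop("unknown variant id in subset")
  new("MRInstruments", data = x@data[i, , drop = FALSE], dropped = x@dropped)
})

setMethod("show", "MRInstruments", function(object) {
  cat("MRInstruments with", nInstruments(object), "instruments\n")
  d <- object@data
  cat("  gamma range: [", signif(min(d$betaExposure), 3), ", ",
      signif(max(d$betaExposure), 3), "]\n", sep = "")
  cat("  Gamma range: [", signif(min(d$betaOutcome), 3), ", ",
      signif(max(d$betaOutcome), 3), "]\n", sep = "")
  if (nrow(object@dropped))
    cat("  dropped:", nrow(object@dropped), "variant(s) (",
        paste(unique(object@dropped$reason), collapse = ", "), ")\n")
})

#' @describeIn MREstimate-class causal estimate.
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @describeIn MREstimate-class standard error.
#' @export
setMethod("mrSE", "MREstimate", function(x) x@se)

#' @describeIn MREstimate-class lower 95% bound.
#' @export
setMethod("ciLower", "MREstimate", function(x) x@ciLower)

#' @describeIn MREstimate-class upper 95% bound.
#' @export
setMethod("ciUpper", "MREstimate", function(x) x@ciUpper)

#' @describeIn MREstimate-class two-sided p-value.
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, J = %d\n",
              object@method, object@beta, object@se, object@ciLower,
              object@ciUpper, object@pvalue, object@nInstruments))
  if (is.finite(object@qStat))
    cat(sprintf("  Q = %.4g, overdispersion = %.4g\n",
                object@qStat, object@overdispersion))
})

#' @describeIn MRTransformed-class transformed point estimate.
#' @export
setMethod("mrBeta", "MRTransformed", function(x) x@value)

#' @describeIn MRTransformed-class lower transformed bound.
#' @export
setMethod("ciLower", "MRTransformed", function(x) x@ciLower)

#' @describeIn MRTransformed-class upper transformed bound.
#' @export
setMethod("ciUpper", "MRTransformed", function(x) x@ciUpper)

setMethod("show", "MRTransformed", function(object) {
  cat(sprintf("MRTransformed [%s]  %.4g (95%% CI %.4g to %.4g)\n",
              object@scaleLabel, object@value, object@ciLower,
              object@ciUpper))
})

setMethod("show", "MRPressoResult", function(object) {
  cat(sprintf("MR-PRESSO (%d simulations, seed %d)\n",
              object@nSim, object@seed))
  cat(sprintf("  global RSS = %.4g, p = %.4g\n",
              object@rssObserved, object@globalP))
  if (length(object@outliers)) {
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion = %.2f%%, p = %.4g\n",
                object@distortionCoef, object@distortionP))
  } else cat("  no outliers flagged\n")
})

setMethod("show", "MRSimConfig", function(object) {
  cat(sprintf("MRSimConfig [%s]  J = %d, nExp = %d, nOut = %d\n",
              object@direction, object@nVariants, object@nExposure,
              object@nOutcome))
  cat(sprintf("  r2 = %.4g, betaCausal = %.4g, prevalence = %.3g, pleiotropy = %s\n",
              object@r2Target, object@betaCausal, object@prevalence,
              object@pleiotropyMode))
})

#' Construct an estimate from summary values
#'
#' Builds an [MREstimate-class] from a point estimate and standard error,
#' with normal-reference 95% interval and p-value — e.g. to feed
#' externally computed estimates into [metaFixed()].
#'
#' @param method method label (scale tag for meta-analysis compatibility).
#' @param beta point estimate.
#' @param se standard error (> 0).
#' @param nInstruments instruments behind the estimate.
#' @return an [MREstimate-class] object.
#' @export
mrEstimate <- function(method, beta, se, nInstruments = 1L) {
  newEstimate(method, beta, se, nInstruments)
}

#' Convert an estimate to a one-row data.frame
#'
#' @param x an [MREstimate-class] object.
#' @return one-row data.frame with method, beta, se, CI bounds, p-value,
#'   instrument count, heterogeneity Q and overdispersion factor.
#' @export
estimateAsData <- function(x) {
  stopifnot(is(x, "MREstimate"))
  data.frame(
    method = x@method, beta = x@beta, se = x@se, ci_low = x@ciLower,
    ci_high = x@ciUpper, pval = x@pvalue, J = x@nInstruments,
    q_stat = x@qStat, overdispersion = x@overdispersion,
    stringsAsFactors = FALSE
  )
}
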