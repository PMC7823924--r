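#' @import methods
#' @importFrom stats approx coef dnorm glm lm mad median pchisq plogis pnorm
#'   qnorm quantile rbinom rnorm runif sd setNames uniroot var binomial
#'   as.formula anova
#' @importFrom utils read.delim write.table
NULL

#' Harmonized instrument set
#'
#' Container for an allele-aligned set of genetic instruments ready for
#' two-sample Mendelian randomization: per variant, the variant-exposure
#' association (gamma, its SE) and the variant-outcome association (Gamma,
#' its SE), expressed for the same effect allele.
#'
#' @slot data data.frame with one row per retained variant and columns
#'   \code{snp}, \code{ea}, \code{oa}, \code{eafExposure}, \code{betaExposure},
#'   \code{seExposure}, \code{eafOutcome}, \code{betaOutcome},
#'   \code{seOutcome}.
#' @slot dropped data.frame with columns \code{snp} and \code{reason}
#'   recording variants removed during harmonization or filtering.
#'
#' @seealso [harmonizeInstruments()], [mrIVW()]
#' @export
setClass("MRInstruments",
  representation(data = "data.frame", dropped = "data.frame"),
  prototype(
    data = data.frame(
      snp = character(), ea = character(), oa = character(),
      eafExposure = numeric(), betaExposure = numeric(),
      seExposure = numeric(), eafOutcome = numeric(),
      betaOutcome = numeric(), seOutcome = numeric(),
      stringsAsFactors = FALSE
    ),
    dropped = data.frame(snp = character(), reason = character(),
                         stringsAsFactors = FALSE)
  )
)

setValidity("MRInstruments", function(object) {
  d <- object@data
  need <- c("snp", "betaExposure", "seExposure", "betaOutcome", "seOutcome")
  if (!all(need %in% names(d)))
    return(paste("data must contain columns:", paste(need, collapse = ", ")))
  if (nrow(d) < 1L) return("at least one instrument is required")
  if (anyDuplicated(d$snp)) return("duplicated variant ids")
  if (any(!is.finite(d$seExposure)) || any(d$seExposure <= 0))
    return("all exposure SEs must be finite and > 0")
  if (any(!is.finite(d$seOutcome)) || any(d$seOutcome <= 0))
    return("all outcome SEs must be finite and > 0")
  if (any(!is.finite(d$betaExposure)) || any(!is.finite(d$betaOutcome)))
    return("all betas must be finite")
  TRUE
})

#' Single-method causal estimate
#'
#' One Mendelian randomization estimator's causal effect estimate with its
#' standard error, 95% confidence interval, p-value and heterogeneity
#' metadata.
#'
#' @slot method character; one of \code{"wald"}, \code{"ivw"},
#'   \code{"egger_slope"}, \code{"egger_intercept"}, \code{"weighted_median"},
#'   \code{"weighted_mode"}.
#' @slot beta causal estimate (log odds ratio or log outcome units per unit
#'   exposure, depending on direction).
#' @slot se standard error of \code{beta}.
#' @slot ciLower,ciUpper 95% confidence bounds.
#' @slot pvalue two-sided p-value from the normal reference.
#' @slot nInstruments number of instruments used.
#' @slot qStat Cochran-type heterogeneity statistic (NA where undefined).
#' @slot overdispersion multiplicative residual scale factor applied to the
#'   SE (floored at 1; exactly 1 under the fixed-effect model).
#' @export
setClass("MREstimate",
  representation(
    method = "character", beta = "numeric", se = "numeric",
    ciLower = "numeric", ciUpper = "numeric", pvalue = "numeric",
    nInstruments = "integer", qStat = "numeric", overdispersion = "numeric"
  ),
  prototype(qStat = NA_real_, overdispersion = 1)
)

setValidity("MREstimate", function(object) {
  if (length(object@method) != 1L) return("method must be length 1")
  if (!is.finite(object@se) || object@se <= 0) return("se must be > 0")
  if (object@ciLower > object@beta || object@beta > object@ciUpper)
    return("beta must lie inside [ciLower, ciUpper]")
  if (object@nInstruments < 1L) return("nInstruments must be >= 1")
  TRUE
})

setClassUnion("MREstimateOrNULL", c("MREstimate", "NULL"))

#' MR-PRESSO result
#'
#' Result of the resampling-based horizontal-pleiotropy battery: the global
#' residual-sum-of-squares test, the per-variant outlier test, and the
#' distortion test comparing causal estimates before and after outlier
#' removal.
#'
#' @slot rssObserved observed inverse-variance-weighted residual sum of
#'   squares from leave-one-out expected outcome effects.
#' @slot globalP Monte-Carlo p-value of the global test (add-one convention,
#'   never exactly zero).
#' @slot perVariantP named vector of Bonferroni-adjusted per-variant outlier
#'   p-values.
#' @slot outliers variant ids flagged at the outlier threshold.
#' @slot betaRaw IVW estimate on all instruments.
#' @slot betaCorrected IVW estimate after removing outliers, or NULL when no
#'   outlier was flagged.
#' @slot distortionCoef percent change
#'   \eqn{100 (\beta_{raw}-\beta_{corr})/|\beta_{corr}|} (NA when no
#'   outliers).
#' @slot distortionP Monte-Carlo p of the distortion test (NA when no
#'   outliers).
#' @slot nSim number of resampling replicates.
#' @slot seed integer seed used.
#' @export
setClass("MRPressoResult",
  representation(
    rssObserved = "numeric", globalP = "numeric", perVariantP = "numeric",
    outliers = "character", betaRaw = "MREstimate",
    betaCorrected = "MREstimateOrNULL", distortionCoef = "numeric",
    distortionP = "numeric", nSim = "integer", seed = "integer"
  )
)

setValidity("MRPressoResult", function(object) {
  lo <- 1 / (object@nSim + 1)
  if (object@globalP < lo - 1e-12 || object@globalP > 1)
    return("globalP outside [1/(nSim+1), 1]")
  if (!all(object@outliers %in% names(object@perVariantP)))
    return("outliers must be a subset of tested variants")
  TRUE
})

#' Transformed causal estimate
#'
#' A causal estimate mapped onto a reporting scale: odds ratio of the
#' outcome per 50% higher exposure (\code{or_per_50pct}) or percent change
#' in the outcome (\code{percent_change}). Confidence bounds are mapped by
#' the same monotone transform.
#'
#' @slot scaleLabel reporting scale label.
#' @slot value point estimate on the reporting scale.
#' @slot ciLower,ciUpper transformed 95% bounds.
#' @export
setClass("MRTransformed",
  representation(scaleLabel = "character", value = "numeric",
                 ciLower = "numeric", ciUpper = "numeric")
)

setValidity("MRTransformed", function(object) {
  if (object@scaleLabel == "or_per_50pct" && object@value <= 0)
    return("odds ratios must be positive")
  if (object@scaleLabel == "percent_change" && object@value <= -100)
    return("percent change must exceed -100")
  TRUE
})

#' Synthetic-data generator configuration
#'
#' Generative ground truth for the two-sample simulator: sample sizes for
#' the disjoint exposure and outcome samples, instrument count and allele
#' frequency range, the fraction of exposure (or liability) variance the
#' instruments explain, the causal effect, outcome case fraction,
#' confounding, and the horizontal-pleiotropy regime.
#'
#' @slot direction \code{"forward"} (continuous exposure, binary outcome)
#'   or \code{"reverse"} (binary liability exposure, continuous outcome).
#' @slot nExposure,nOutcome individuals in the two non-overlapping samples.
#' @slot nVariants number of independent instruments J.
#' @slot mafRange minor allele frequency range, within (0, 0.5].
#' @slot r2Target fraction of exposure (forward) or liability (reverse)
#'   variance explained by the instruments jointly.
#' @slot betaCausal causal effect: log-odds of the outcome per unit
#'   exposure (forward); outcome units per unit liability (reverse).
#' @slot prevalence case fraction of the binary trait in (0,1).
#' @slot confounderEffects length-2 numeric: effect of the shared standard
#'   normal confounder U on exposure and on outcome (liability/log-odds
#'   scale).
#' @slot pleiotropyMode one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"correlated"}.
#' @slot pleiotropyMean,pleiotropySD mean and SD of the direct
#'   variant-outcome effects alpha.
#' @slot seed integer seed.
#' @seealso [simulationConfig()], [simulateTwoSample()]
#' @export
setClass("MRSimConfig",
  representation(
    direction = "character", nExposure = "integer", nOutcome = "integer",
    nVariants = "integer", mafRange = "numeric", r2Target = "numeric",
    betaCausal = "numeric", prevalence = "numeric",
    confounderEffects = "numeric", pleiotropyMode = "character",
    pleiotropyMean = "numeric", pleiotropySD = "numeric", seed = "integer"
  )
)

setValidity("MRSimConfig", function(object) {
  if (!object@direction %in% c("forward", "reverse"))
    return("direction must be 'forward' or 'reverse'")
  if (object@nVariants < 1L) return("nVariants must be >= 1")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    return("mafRange must be an increasing pair within (0, 0.5]")
  if (object@r2Target < 0 || object@r2Target >= 1)
    return("r2Target must be in [0, 1)")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence must be in (0, 1)")
  if (length(object@confounderEffects) != 2L)
    return("confounderEffects must have length 2 (exposure, outcome)")
  if (!object@pleiotropyMode %in%
      c("none", "balanced", "directional", "correlated"))
    return("unknown pleiotropyMode")
  if (object@pleiotropySD < 0) return("pleiotropySD must be >= 0")
  TRUE
})
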