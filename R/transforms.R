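#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines estimates of the same quantity (e.g. the same method applied
#' to two outcome cohorts) with weights \eqn{1/se^2}. With only two
#' cohorts this is the standard, stable choice; mixing methods (different
#' \code{method} labels, hence different scales) is refused.
#'
#' @param estimates list of [MREstimate-class] objects.
#' @return an [MREstimate-class] with the shared method label.
#' @examples
#' e1 <- waldRatio(1, 0.1, 1, 1)
#' e2 <- waldRatio(1, 0.1, 0, 1)
#' mrBeta(metaFixed(list(e1, e2)))  # 0.5
#' @export
metaFixed <- function(estimates) {
  if (!length(estimates)) stop("empty estimate list")
  stopifnot(all(vapply(estimates, is, logical(1), "MREstimate")))
  methods <- vapply(estimates, function(e) e@method, character(1))
  if (length(unique(methods)) != 1L)
    stop("cannot meta-analyse estimates on different scales: ",
         paste(unique(methods), collapse = ", "))
  b <- vapply(estimates, mrBeta, numeric(1))
  se <- vapply(estimates, mrSE, numeric(1))
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  newEstimate(methods[1], beta, 1 / sqrt(sum(w)),
              sum(vapply(estimates, function(e) e@nInstruments, integer(1))))
}

#' @rdname orPer50
#' @export
setGeneric("orPer50", function(x, ...) standardGeneric("orPer50"))

#' Odds ratio per 50% higher exposure
#'
#' Maps a log odds ratio per unit of natural-log exposure onto the odds
#' ratio per 50% higher exposure via the converting factor
#' \eqn{1.5^{\beta}}; confidence bounds are mapped by the same monotone
#' transform.
#'
#' @param x numeric log-OR per log unit, or an [MREstimate-class].
#' @param ciLow,ciHigh 95% bounds (numeric input only).
#' @param ... unused.
#' @return an [MRTransformed-class] with scale \code{"or_per_50pct"}.
#' @examples
#' mrBeta(orPer50(log(0.97) / log(1.5)))  # 0.97
#' @export
setMethod("orPer50", "numeric", function(x, ciLow = NA_real_,
                                         ciHigh = NA_real_, ...) {
  new("MRTransformed", scaleLabel = "or_per_50pct", value = 1.5^x,
      ciLower = 1.5^ciLow, ciUpper = 1.5^ciHigh)
})

#' @rdname orPer50
#' @export
setMethod("orPer50", "MREstimate", function(x, ...) {
  orPer50(mrBeta(x), ciLower(x), ciUpper(x))
})

#' @rdname percentChange
#' @export
setGeneric("percentChange", function(x, ...) standardGeneric("percentChange"))

#' Percent change in the outcome
#'
#' Maps an effect on the natural-log outcome scale onto a percent change,
#' \eqn{100(\exp(\beta) - 1)}; confidence bounds are mapped identically.
#'
#' @param x numeric log-scale effect, or an [MREstimate-class].
#' @param ciLow,ciHigh 95% bounds (numeric input only).
#' @param ... unused.
#' @return an [MRTransformed-class] with scale \code{"percent_change"}.
#' @examples
#' mrBeta(percentChange(log(0.9)))  # -10
#' @export
setMethod("percentChange", "numeric", function(x, ciLow = NA_real_,
                                               ciHigh = NA_real_, ...) {
  new("MRTransformed", scaleLabel = "percent_change",
      value = 100 * (exp(x) - 1), ciLower = 100 * (exp(ciLow) - 1),
      ciUpper = 100 * (exp(ciHigh) - 1))
})

#' @rdname percentChange
#' @export
setMethod("percentChange", "MREstimate", function(x, ...) {
  percentChange(mrBeta(x), ciLower(x), ciUpper(x))
})

#' Power of a two-sample MR study with a binary outcome
#'
#' Uses the standard non-centrality approximation: the IVW log-OR per SD
#' of exposure has approximate standard error
#' \eqn{SE = 1/\sqrt{n \cdot r^2 \cdot K(1-K)}} where n is the outcome
#' sample size, \eqn{r^2} the exposure variance explained by the
#' instruments and K the case fraction. Achieved power for a given effect
#' uses the exact two-sided normal formula (so power at \eqn{\beta = 0}
#' equals \eqn{\alpha}); the minimal detectable effect at a target power
#' uses the closed form \eqn{|\beta| = (z_{1-\alpha/2} + z_{power}) SE},
#' which scales exactly as \eqn{1/\sqrt{n}}. If \code{sdLogExposure} is
#' supplied the detectable effect is also reported as an odds ratio per
#' 50% higher exposure.
#'
#' @param n outcome sample size.
#' @param r2 exposure variance explained by the instruments, in (0,1).
#' @param caseFraction case fraction K in (0,1).
#' @param alpha two-sided significance level (default 0.05).
#' @param beta true log-OR per SD of exposure; supply to compute power.
#' @param power target power; supply to compute the detectable effect
#'   (default 0.8 when \code{beta} is NULL).
#' @param sdLogExposure SD of the natural-log exposure, used to express
#'   the detectable effect per 50% higher exposure (optional; the
#'   motivating study never reports it, so it is an explicit input).
#' @return list with \code{se} and either \code{power} or
#'   \code{detectableBeta} (per SD; both signs detectable), plus
#'   \code{detectableORper50} (and its protective reciprocal direction
#'   \code{detectableORper50Lower}) when \code{sdLogExposure} is given.
#' @export
mrPowerBinary <- function(n, r2, caseFraction, alpha = 0.05, beta = NULL,
                          power = NULL, sdLogExposure = NULL) {
  stopifnot(n >= 1, r2 > 0, r2 < 1, caseFraction > 0, caseFraction < 1,
            alpha > 0, alpha < 1)
  se <- 1 / sqrt(n * r2 * caseFraction * (1 - caseFraction))
  z <- qnorm(1 - alpha / 2)
  if (!is.null(beta)) {
    pw <- pnorm(abs(beta) / se - z) + pnorm(-abs(beta) / se - z)
    return(list(se = se, power = pw))
  }
  if (is.null(power)) power <- 0.8
  stopifnot(power > 0, power < 1)
  det <- (z + qnorm(power)) * se
  out <- list(se = se, detectableBeta = det)
  if (!is.null(sdLogExposure)) {
    stopifnot(sdLogExposure > 0)
    perLog <- det / sdLogExposure
    out$detectableORper50 <- 1.5^perLog
    out$detectableORper50Lower <- 1.5^(-perLog)
  }
  out
}
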