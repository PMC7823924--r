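#' Leave-one-out analysis
#'
#' Recomputes the IVW estimate excluding each instrument in turn, using
#' the same effects model as the headline estimate so rows are comparable.
#' The final row (\code{excluded = "(none)"}) is the all-variant estimate.
#'
#' @param object an [MRInstruments-class] object with at least 2
#'   instruments.
#' @param effectsModel IVW effects model (default multiplicative).
#' @return data.frame with columns \code{excluded}, \code{beta}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{pval}, \code{J}.
#' @export
leaveOneOut <- function(object, effectsModel = "multiplicative") {
  stopifnot(is(object, "MRInstruments"))
  snps <- variantIds(object)
  J <- length(snps)
  if (J < 2) stop("leave-one-out requires at least 2 instruments")
  one <- function(est, label) {
    cbind(data.frame(excluded = label, stringsAsFactors = FALSE),
          estimateAsData(est)[, c("beta", "se", "ci_low", "ci_high",
                                  "pval", "J")])
  }
  rows <- lapply(seq_len(J), function(j)
    one(mrIVW(object[-j], effectsModel), snps[j]))
  rows[[J + 1]] <- one(mrIVW(object, effectsModel), "(none)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-variant forest table
#'
#' One Wald-ratio row per instrument plus the IVW summary row, the data
#' behind a single-variant forest plot.
#'
#' @param object an [MRInstruments-class] object; all exposure effects
#'   must be non-zero.
#' @param effectsModel IVW effects model for the summary row.
#' @return data.frame with columns \code{snp}, \code{beta}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{pval}.
#' @export
singleSnpForest <- function(object, effectsModel = "multiplicative") {
  stopifnot(is(object, "MRInstruments"))
  g <- exposureBeta(object); sg <- exposureSE(object)
  G <- outcomeBeta(object); sG <- outcomeSE(object)
  if (any(g == 0)) stop("Wald ratio undefined for variant(s) with zero exposure effect")
  snps <- variantIds(object)
  rows <- lapply(seq_along(snps), function(j) {
    e <- waldRatio(g[j], sg[j], G[j], sG[j])
    data.frame(snp = snps[j], beta = mrBeta(e), se = mrSE(e),
               ci_low = ciLower(e), ci_high = ciUpper(e), pval = pValue(e),
               stringsAsFactors = FALSE)
  })
  ivw <- mrIVW(object, effectsModel)
  rows[[length(rows) + 1]] <- data.frame(
    snp = "IVW (all)", beta = mrBeta(ivw), se = mrSE(ivw),
    ci_low = ciLower(ivw), ci_high = ciUpper(ivw), pval = pValue(ivw),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
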