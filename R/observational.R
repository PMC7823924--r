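tierCovariates <- function(tier = c("basic", "socioeconomic", "lifestyle")) {
  tier <- match.arg(tier)
  switch(tier,
         basic = c("ageGroup", "sex"),
         socioeconomic = c("ageGroup", "sex", "sesScore"),
         lifestyle = c("ageGroup", "sex", "sesScore", "lifestyleScore"))
}

#' Categorize serum 25(OH)D concentrations
#'
#' Clinical categories in nmol/L: \code{"<25"}, \code{">=25 and <50"},
#' \code{">=50 and <75"}, \code{">75"}. The boundary value 75 is assigned
#' to the third category (the top category is strictly above 75). The
#' lowest category is the reference level.
#'
#' @param values concentrations in nmol/L; must be positive.
#' @return factor with the four category labels.
#' @examples
#' categorize25OHD(c(24.9, 25, 75, 75.1))
#' @export
categorize25OHD <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("25(OH)D concentrations must be positive and finite")
  labs <- c("<25", ">=25 and <50", ">=50 and <75", ">75")
  idx <- ifelse(values < 25, 1L,
         ifelse(values < 50, 2L,
         ifelse(values <= 75, 3L, 4L)))
  factor(labs[idx], levels = labs)
}

obsFit <- function(cohort, rhs) {
  f <- as.formula(paste("depression ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = cohort, family = binomial()))
  if (!fit$converged)
    stop("logistic model did not converge for: ", deparse(f))
  se <- sqrt(diag(summary(fit)$cov.scaled))
  if (any(!is.finite(se)) || any(se > 100))
    stop("apparent separation in logistic model for: ", deparse(f))
  fit
}

lrtP <- function(fit0, fit1) {
  stat <- fit0$deviance - fit1$deviance
  df <- fit0$df.residual - fit1$df.residual
  pchisq(pmax(stat, 0), df, lower.tail = FALSE)
}

#' Tiered logistic models of depression on 25(OH)D
#'
#' Maximum-likelihood logistic regression of depression on serum 25(OH)D
#' with cumulative covariate adjustment tiers (basic: age group and sex;
#' socioeconomic: + socioeconomic score; lifestyle: + lifestyle score).
#' With \code{exposureForm = "continuous"} the natural-log 25(OH)D
#' coefficient is reported as an odds ratio per 50% higher 25(OH)D; with
#' \code{"categorical"} odds ratios are reported against the
#' \code{"<25"} nmol/L reference. The exposure term's likelihood-ratio
#' p-value is attached as attribute \code{"pLRT"}.
#'
#' @param cohort data.frame from [simulateObservationalCohort()] (or any
#'   table with the same columns).
#' @param exposureForm \code{"continuous"} or \code{"categorical"}.
#' @param tier \code{"basic"}, \code{"socioeconomic"} or
#'   \code{"lifestyle"}.
#' @return data.frame with one row per exposure term: \code{term},
#'   \code{beta} (log-OR), \code{or}, \code{ci_low}, \code{ci_high}
#'   (OR scale), \code{pval} (Wald); plus attribute \code{"pLRT"}.
#' @export
fitTieredLogistic <- function(cohort,
                              exposureForm = c("continuous", "categorical"),
                              tier = "basic") {
  exposureForm <- match.arg(exposureForm)
  if (length(unique(cohort$depression)) < 2)
    stop("both outcome classes must be present")
  covs <- tierCovariates(tier)
  if (exposureForm == "continuous") {
    fit1 <- obsFit(cohort, c("ln_25ohd", covs))
    fit0 <- obsFit(cohort, covs)
    sm <- summary(fit1)$coefficients["ln_25ohd", ]
    tr <- orPer50(sm[1], sm[1] - qnorm(0.975) * sm[2],
                  sm[1] + qnorm(0.975) * sm[2])
    out <- data.frame(
      term = "per 50% higher 25(OH)D", beta = unname(sm[1]),
      or = mrBeta(tr), ci_low = ciLower(tr), ci_high = ciUpper(tr),
      pval = unname(sm[4]), stringsAsFactors = FALSE)
  } else {
    cohort$vitdCat <- categorize25OHD(cohort$vitd_nmol)
    fit1 <- obsFit(cohort, c("vitdCat", covs))
    fit0 <- obsFit(cohort, covs)
    cf <- summary(fit1)$coefficients
    rows <- grep("^vitdCat", rownames(cf))
    z <- qnorm(0.975)
    out <- data.frame(
      term = c("<25 (reference)",
               sub("^vitdCat", "", rownames(cf)[rows])),
      beta = c(0, cf[rows, 1]),
      or = c(1, exp(cf[rows, 1])),
      ci_low = c(NA, exp(cf[rows, 1] - z * cf[rows, 2])),
      ci_high = c(NA, exp(cf[rows, 1] + z * cf[rows, 2])),
      pval = c(NA, cf[rows, 4]), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "pLRT") <- lrtP(fit0, fit1)
  out
}

#' Trend, curvature and interaction tests
#'
#' Likelihood-ratio tests around the continuous log-exposure logistic
#' model at a given adjustment tier: \code{pTrend} for the linear
#' log-25(OH)D term; \code{pCurvature} for adding a squared log-exposure
#' term to the linear model; \code{pInteractionSex} and
#' \code{pInteractionAge} for exposure-by-sex and exposure-by-age-group
#' product terms.
#'
#' @inheritParams fitTieredLogistic
#' @return named numeric vector with elements \code{pTrend},
#'   \code{pCurvature}, \code{pInteractionSex}, \code{pInteractionAge}.
#' @export
trendCurvatureInteraction <- function(cohort, tier = "basic") {
  covs <- tierCovariates(tier)
  cohort$lnsq <- cohort$ln_25ohd^2
  fit0 <- obsFit(cohort, covs)
  fitL <- obsFit(cohort, c("ln_25ohd", covs))
  fitQ <- obsFit(cohort, c("ln_25ohd", "lnsq", covs))
  fitS <- obsFit(cohort, c("ln_25ohd", covs, "ln_25ohd:sex"))
  fitA <- obsFit(cohort, c("ln_25ohd", covs, "ln_25ohd:ageGroup"))
  c(pTrend = lrtP(fit0, fitL),
    pCurvature = lrtP(fitL, fitQ),
    pInteractionSex = lrtP(fitL, fitS),
    pInteractionAge = lrtP(fitL, fitA))
}

#' Prevalence and 25(OH)D tabulation by group
#'
#' Per-group membership counts and percentages, depression case counts
#' and percentages, and the median (IQR) of serum 25(OH)D, in the style
#' of a cohort characteristics table. Percentages are rounded half-up to
#' one decimal place. Empty groups are emitted with n = 0 and blank
#' statistics.
#'
#' @param cohort individual-level data.frame with columns
#'   \code{depression} and \code{vitd_nmol}.
#' @param by name of the grouping column.
#' @return data.frame with columns \code{group}, \code{n}, \code{pct},
#'   \code{cases}, \code{casePct}, \code{median}, \code{q1}, \code{q3}.
#' @export
tabulatePrevalence <- function(cohort, by) {
  if (!by %in% names(cohort)) stop("grouping column not found: ", by)
  g <- cohort[[by]]
  levelsOf <- if (is.factor(g)) levels(g) else sort(unique(g))
  total <- nrow(cohort)
  rows <- lapply(levelsOf, function(lv) {
    sel <- !is.na(g) & g == lv
    n <- sum(sel)
    if (n == 0)
      return(data.frame(group = as.character(lv), n = 0L, pct = 0,
                        cases = 0L, casePct = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        stringsAsFactors = FALSE))
    cases <- sum(cohort$depression[sel])
    qs <- quantile(cohort$vitd_nmol[sel], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = as.character(lv), n = n,
               pct = roundHalfUp(100 * n / total, 1), cases = cases,
               casePct = roundHalfUp(100 * cases / n, 1),
               median = qs[2], q1 = qs[1], q3 = qs[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentages from printed group counts
#'
#' Computes group membership and case percentages directly from counts,
#' e.g. counts printed in a published cohort characteristics table, with
#' half-up rounding to one decimal place.
#'
#' @param counts data.frame with columns \code{group}, \code{n} and
#'   optionally \code{cases}.
#' @param total denominator for membership percentages (default
#'   \code{sum(counts$n)}).
#' @return \code{counts} with added \code{pct} and (when cases are
#'   present) \code{casePct} columns.
#' @export
tabulateCounts <- function(counts, total = sum(counts$n)) {
  stopifnot(all(c("group", "n") %in% names(counts)), total > 0)
  counts$pct <- roundHalfUp(100 * counts$n / total, 1)
  if ("cases" %in% names(counts))
    counts$casePct <- roundHalfUp(100 * counts$cases / counts$n, 1)
  counts
}
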