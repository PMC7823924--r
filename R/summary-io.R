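#' Read GWAS summary statistics
#'
#' Reads a tab-separated table of per-variant association summaries with a
#' header row. The canonical dialect has columns
#' \code{snp ea oa eaf beta se pval n} with optional \code{info} and
#' \code{hwe_p}; \code{"."} marks a missing value. Other headers can be
#' mapped via \code{columnMap}.
#'
#' Every record is validated: alleles must be single bases A/C/G/T and
#' distinct, \code{se} strictly positive, \code{eaf} strictly inside (0,1)
#' when present, \code{pval} in (0,1]. Offending rows are reported by row
#' number and reading fails.
#'
#' @param path path to a TSV file.
#' @param columnMap optional named character vector mapping canonical names
#'   (names) to file column names (values), e.g.
#'   \code{c(snp = "rsid", beta = "b")}.
#' @return data.frame of validated variant associations in canonical
#'   column order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeSummaryStats(data.frame(
#'   snp = "rs1", ea = "A", oa = "G", eaf = 0.3,
#'   beta = 0.1, se = 0.02, pval = 1e-8, n = 1000L), f)
#' readSummaryStats(f)
#' @export
readSummaryStats <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columnMap)) {
    miss <- setdiff(unname(columnMap), names(raw))
    if (length(miss))
      stop("mapped column(s) absent from file: ", paste(miss, collapse = ", "))
    idx <- match(unname(columnMap), names(raw))
    names(raw)[idx] <- names(columnMap)
  }
  mandatory <- c("snp", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("eaf", "beta", "se", "pval", "n", "info", "hwe_p")) {
    if (col %in% names(raw)) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  validateAssociations(raw)
  keep <- intersect(c(mandatory, "info", "hwe_p"), names(raw))
  raw[, keep, drop = FALSE]
}

validateAssociations <- function(x) {
  bad <- function(cond) which(cond | is.na(cond))
  problems <- character()
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0("row(s) ", paste(rows, collapse = ","),
                                      ": ", what))
  }
  bases <- c("A", "C", "G", "T")
  note(bad(!(toupper(x$ea) %in% bases)), "effect allele not one of A/C/G/T")
  note(bad(!(toupper(x$oa) %in% bases)), "other allele not one of A/C/G/T")
  note(which(toupper(x$ea) == toupper(x$oa)), "effect and other allele identical")
  note(bad(!is.finite(x$beta)), "non-numeric beta")
  note(c(bad(!is.finite(x$se)), which(is.finite(x$se) & x$se <= 0)),
       "se missing or <= 0")
  if (!all(is.na(x$eaf)))
    note(which(is.finite(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)),
         "eaf outside (0,1)")
  note(which(is.finite(x$pval) & (x$pval <= 0 | x$pval > 1)),
       "pval outside (0,1]")
  if (length(problems))
    stop("invalid summary records:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Write GWAS summary statistics
#'
#' Writes the canonical tab-separated dialect used by [readSummaryStats()];
#' missing values are written as \code{"."}.
#'
#' @param x data.frame of variant associations.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSummaryStats <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Filter instruments on QC thresholds
#'
#' Applies the instrument quality filters: minor allele frequency, optional
#' Hardy-Weinberg p, optional imputation INFO score, and association
#' p-value. All thresholds are inclusive (a record exactly at the threshold
#' is kept). Records missing an optional metric pass that filter. Each
#' dropped record carries its first failing reason, in the order
#' maf, hwe, info, pval.
#'
#' @param records data.frame from [readSummaryStats()].
#' @param mafMin minimum minor allele frequency \code{min(eaf, 1-eaf)}
#'   (default 0: off). The strong vitamin D instruments in the motivating
#'   study all satisfy 0.18.
#' @param hwePMin minimum Hardy-Weinberg p-value (default 0: off).
#' @param infoMin minimum imputation INFO score (default 0: off).
#' @param pvalMax maximum association p-value (default 1: off).
#' @return list with \code{kept} (data.frame) and \code{dropped}
#'   (data.frame of snp, reason).
#' @export
filterInstruments <- function(records, mafMin = 0, hwePMin = 0,
                              infoMin = 0, pvalMax = 1) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, hwePMin >= 0, hwePMin <= 1,
            infoMin >= 0, infoMin <= 1, pvalMax > 0, pvalMax <= 1)
  maf <- pmin(records$eaf, 1 - records$eaf)
  failMaf <- is.finite(maf) & maf < mafMin
  hwe <- if ("hwe_p" %in% names(records)) records$hwe_p else rep(NA_real_, nrow(records))
  failHwe <- is.finite(hwe) & hwe < hwePMin
  info <- if ("info" %in% names(records)) records$info else rep(NA_real_, nrow(records))
  failInfo <- is.finite(info) & info < infoMin
  failP <- is.finite(records$pval) & records$pval > pvalMax
  reason <- rep(NA_character_, nrow(records))
  reason[failP] <- "pval"
  reason[failInfo] <- "info"
  reason[failHwe] <- "hwe"
  reason[failMaf] <- "maf"
  drop <- !is.na(reason)
  list(
    kept = records[!drop, , drop = FALSE],
    dropped = data.frame(snp = records$snp[drop], reason = reason[drop],
                         stringsAsFactors = FALSE)
  )
}

isPalindromic <- function(ea, oa) {
  p <- paste0(toupper(ea), toupper(oa))
  p %in% c("AT", "TA", "CG", "GC")
}

flipAllele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome-side effects to the exposure's effect allele, matched by
#' variant id. Outcome records whose effect/other alleles are swapped
#' relative to the exposure (directly or as the complementary strand) have
#' their beta sign flipped and eaf replaced by 1 - eaf. Strand-ambiguous
#' palindromic variants (A/T or C/G) cannot be aligned by allele labels;
#' they are kept only when both allele frequencies fall on the same side of
#' 0.5 and outside the ambiguity window \code{[0.5 - w, 0.5 + w]}, in which
#' case the effect alleles are inferred to coincide and no flip is applied;
#' otherwise they are dropped with reason \code{"palindromic"}. Variants
#' absent from either table are dropped with reason \code{"missing"};
#' incompatible allele pairs with reason \code{"allele_mismatch"}.
#'
#' @param exposure,outcome data.frames from [readSummaryStats()].
#' @param palindromeWindow half-width w of the eaf ambiguity window around
#'   0.5 (default 0.08).
#' @return an [MRInstruments-class] object.
#' @export
harmonizeInstruments <- function(exposure, outcome, palindromeWindow = 0.08) {
  stopifnot(palindromeWindow >= 0, palindromeWindow < 0.5)
  common <- intersect(exposure$snp, outcome$snp)
  if (!length(common)) stop("no variants shared between exposure and outcome")
  droppedSnp <- setdiff(exposure$snp, common)
  dropped <- data.frame(snp = droppedSnp,
                        reason = rep("missing", length(droppedSnp)),
                        stringsAsFactors = FALSE)
  ex <- exposure[match(common, exposure$snp), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp), , drop = FALSE]
  exEa <- toupper(ex$ea); exOa <- toupper(ex$oa)
  ouEa <- toupper(ou$ea); ouOa <- toupper(ou$oa)

  pal <- isPalindromic(exEa, exOa)
  same <- (ouEa == exEa & ouOa == exOa) |
    (flipAllele(ouEa) == exEa & flipAllele(ouOa) == exOa)
  swap <- (ouEa == exOa & ouOa == exEa) |
    (flipAllele(ouEa) == exOa & flipAllele(ouOa) == exEa)

  keep <- logical(length(common))
  flip <- logical(length(common))
  reason <- rep(NA_character_, length(common))
  w <- palindromeWindow
  for (k in seq_along(common)) {
    if (pal[k]) {
      eafX <- ex$eaf[k]; eafY <- ou$eaf[k]
      outside <- abs(eafX - 0.5) > w && abs(eafY - 0.5) > w
      sameSide <- sign(eafX - 0.5) == sign(eafY - 0.5)
      if (outside && sameSide) {
        keep[k] <- TRUE        # effect alleles inferred identical
      } else reason[k] <- "palindromic"
    } else if (same[k]) {
      keep[k] <- TRUE
    } else if (swap[k]) {
      keep[k] <- TRUE; flip[k] <- TRUE
    } else {
      reason[k] <- "allele_mismatch"
    }
  }
  if (any(!keep))
    dropped <- rbind(dropped, data.frame(snp = common[!keep],
                                         reason = reason[!keep],
                                         stringsAsFactors = FALSE))
  if (!any(keep)) stop("no variants remain after harmonization")

  betaOut <- ifelse(flip, -ou$beta, ou$beta)[keep]
  eafOut <- ifelse(flip, 1 - ou$eaf, ou$eaf)[keep]
  data <- data.frame(
    snp = common[keep], ea = exEa[keep], oa = exOa[keep],
    eafExposure = ex$eaf[keep], betaExposure = ex$beta[keep],
    seExposure = ex$se[keep], eafOutcome = eafOut,
    betaOutcome = betaOut, seOutcome = ou$se[keep],
    stringsAsFactors = FALSE
  )
  rownames(data) <- NULL
  new("MRInstruments", data = data, dropped = dropped)
}

#' Construct an instrument set from effect vectors
#'
#' Convenience constructor used in simulations and tests when allele
#' bookkeeping is not at stake: builds an [MRInstruments-class] object
#' directly from the four effect/SE vectors.
#'
#' @param gamma,seGamma variant-exposure effects and SEs.
#' @param Gamma,seGammaOut variant-outcome effects and SEs.
#' @param snps optional variant ids (default \code{snp1..snpJ}).
#' @return an [MRInstruments-class] object.
#' @export
makeInstruments <- function(gamma, seGamma, Gamma, seGammaOut, snps = NULL) {
  J <- length(gamma)
  stopifnot(length(seGamma) == J, length(Gamma) == J,
            length(seGammaOut) == J)
  if (is.null(snps)) snps <- paste0("snp", seq_len(J))
  new("MRInstruments", data = data.frame(
    snp = snps, ea = rep("A", J), oa = rep("G", J),
    eafExposure = rep(0.3, J), betaExposure = gamma, seExposure = seGamma,
    eafOutcome = rep(0.3, J), betaOutcome = Gamma, seOutcome = seGammaOut,
    stringsAsFactors = FALSE
  ))
}

#' Instrument set as harmonized summary tables
#'
#' Returns the harmonized pair of summary tables (exposure side, outcome
#' side) in the canonical dialect, e.g. for re-harmonization or export.
#'
#' @param x an [MRInstruments-class] object.
#' @return list of two data.frames, \code{exposure} and \code{outcome}.
#' @export
instrumentTables <- function(x) {
  stopifnot(is(x, "MRInstruments"))
  d <- x@data
  list(
    exposure = data.frame(snp = d$snp, ea = d$ea, oa = d$oa,
                          eaf = d$eafExposure, beta = d$betaExposure,
                          se = d$seExposure, pval = 2 * pnorm(-abs(d$betaExposure / d$seExposure)),
                          n = NA_real_, stringsAsFactors = FALSE),
    outcome = data.frame(snp = d$snp, ea = d$ea, oa = d$oa,
                         eaf = d$eafOutcome, beta = d$betaOutcome,
                         se = d$seOutcome, pval = 2 * pnorm(-abs(d$betaOutcome / d$seOutcome)),
                         n = NA_real_, stringsAsFactors = FALSE)
  )
}
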