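#' Configure one analysis direction
#'
#' Bundles everything needed to run one direction of the bi-directional
#' analysis: the exposure instrument table, one or more outcome cohorts
#' (the two-cohort case mirrors analysing a biobank and a consortium and
#' then meta-analysing), optional named instrument subsets (e.g. variants
#' in synthesis genes vs the rest), the estimator battery, QC thresholds,
#' the reporting-scale transform, and seeds.
#'
#' @param label direction label, e.g. \code{"25OHD->depression"}.
#' @param exposure exposure summary table (data.frame) or TSV path.
#' @param cohorts named list of outcome summary tables (data.frames) or
#'   TSV paths; at least one.
#' @param subsets optional named list of variant-id vectors; variants in
#'   no subset form an automatic complement subset \code{"other"}.
#' @param methods estimators to run, subset of
#'   \code{c("ivw", "egger", "median", "mode")}.
#' @param transform \code{"none"}, \code{"or_per_50pct"} or
#'   \code{"percent_change"}.
#' @param mafMin,hwePMin,infoMin,pvalMax instrument QC thresholds passed
#'   to [filterInstruments()].
#' @param palindromeWindow harmonization ambiguity window.
#' @param nBoot bootstrap replicates for median/mode.
#' @param nSim MR-PRESSO replicates.
#' @param runPresso,runDiagnostics switch the PRESSO and leave-one-out
#'   stages (skipped automatically when J is too small).
#' @param seed integer seed for all resampling.
#' @return an object of class \code{mrAnalysisConfig}.
#' @export
analysisConfig <- function(label, exposure, cohorts, subsets = list(),
                           methods = c("ivw", "egger", "median", "mode"),
                           transform = c("none", "or_per_50pct",
                                         "percent_change"),
                           mafMin = 0, hwePMin = 0, infoMin = 0,
                           pvalMax = 1, palindromeWindow = 0.08,
                           nBoot = 1000, nSim = 1000, runPresso = TRUE,
                           runDiagnostics = TRUE, seed = 1) {
  transform <- match.arg(transform)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(cohorts)) stop("at least one outcome cohort is required")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stop("cohorts must be a named list")
  if (length(subsets) && (is.null(names(subsets)) ||
                          any(!nzchar(names(subsets)))))
    stop("subsets must be named")
  structure(list(
    label = label, exposure = exposure, cohorts = cohorts,
    subsets = subsets, methods = methods, transform = transform,
    mafMin = mafMin, hwePMin = hwePMin, infoMin = infoMin,
    pvalMax = pvalMax, palindromeWindow = palindromeWindow,
    nBoot = nBoot, nSim = nSim, runPresso = runPresso,
    runDiagnostics = runDiagnostics, seed = as.integer(seed)
  ), class = "mrAnalysisConfig")
}

loadSummary <- function(x) {
  if (is.character(x)) readSummaryStats(x) else x
}

applyTransform <- function(df, transform) {
  if (transform == "none" || !nrow(df)) {
    df$transformed <- NA_real_
    df$transformed_low <- NA_real_
    df$transformed_high <- NA_real_
    df$scale <- "log"
    return(df)
  }
  fun <- if (transform == "or_per_50pct") orPer50 else percentChange
  tr <- lapply(seq_len(nrow(df)), function(i) {
    # pleiotropy intercepts stay on the log scale: they are not causal
    # effects of the exposure
    if (df$method[i] == "egger_intercept") return(c(NA, NA, NA))
    t <- fun(df$beta[i], df$ci_low[i], df$ci_high[i])
    c(mrBeta(t), ciLower(t), ciUpper(t))
  })
  tr <- do.call(rbind, tr)
  df$transformed <- tr[, 1]
  df$transformed_low <- tr[, 2]
  df$transformed_high <- tr[, 3]
  df$scale <- ifelse(df$method == "egger_intercept", "log", transform)
  df
}

estimateStage <- function(set, config, cohortName, subsetName) {
  res <- tryCatch(
    mrEstimateAll(set, methods = config$methods, nBoot = config$nBoot,
                  seed = config$seed),
    error = function(e) NULL)
  if (is.null(res)) {
    # subset too small for part of the battery: keep whatever runs
    res <- do.call(rbind, lapply(config$methods, function(m) {
      tryCatch(mrEstimateAll(set, methods = m, nBoot = config$nBoot,
                             seed = config$seed),
               error = function(e) NULL)
    }))
  }
  if (is.null(res) || !nrow(res)) return(NULL)
  cbind(data.frame(direction = config$label, cohort = cohortName,
                   subset = subsetName, stringsAsFactors = FALSE), res)
}

#' Run one direction of the analysis
#'
#' Pipeline per outcome cohort: read, QC-filter the exposure instruments,
#' harmonize, run the estimator battery (on the full set and on each
#' configured instrument subset), MR-PRESSO, leave-one-out and
#' single-variant diagnostics, apply the reporting-scale transform, then
#' fixed-effect meta-analysis of each method across cohorts. Every stage
#' failure is re-thrown tagged with the stage name.
#'
#' @param config an \code{mrAnalysisConfig} from [analysisConfig()].
#' @return list with elements \code{label}, \code{results} (data.frame of
#'   per-cohort and meta-analysed estimates), \code{presso},
#'   \code{leaveOneOut}, \code{forest}, \code{dropped} (per-cohort lists)
#'   and \code{instruments} (per-cohort [MRInstruments-class]).
#' @export
runDirection <- function(config) {
  stopifnot(inherits(config, "mrAnalysisConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  exposure <- stage("read_exposure", loadSummary(config$exposure))
  filt <- stage("filter", filterInstruments(
    exposure, mafMin = config$mafMin, hwePMin = config$hwePMin,
    infoMin = config$infoMin, pvalMax = config$pvalMax))
  exposure <- filt$kept
  allRes <- list()
  presso <- list(); loo <- list(); forest <- list()
  droppedL <- list(); instruments <- list()

  for (cohortName in names(config$cohorts)) {
    outcome <- stage(paste0("read_outcome:", cohortName),
                     loadSummary(config$cohorts[[cohortName]]))
    set <- stage(paste0("harmonize:", cohortName),
                 harmonizeInstruments(exposure, outcome,
                                      config$palindromeWindow))
    set@dropped <- rbind(filt$dropped, set@dropped)
    instruments[[cohortName]] <- set
    droppedL[[cohortName]] <- set@dropped

    subsets <- config$subsets
    if (length(subsets)) {
      used <- unique(unlist(subsets))
      unknown <- setdiff(used, variantIds(set))
      if (length(unknown))
        stop("[subset] unknown variant id(s): ",
             paste(unknown, collapse = ", "))
      rest <- setdiff(variantIds(set), used)
      if (length(rest)) subsets$other <- rest
    }
    runs <- c(list(all = variantIds(set)), subsets)
    for (sn in names(runs)) {
      sub <- set[intersect(variantIds(set), runs[[sn]])]
      allRes[[paste(cohortName, sn)]] <-
        stage(paste0("estimate:", cohortName, ":", sn),
              estimateStage(sub, config, cohortName, sn))
    }
    if (config$runPresso && nInstruments(set) >= 4)
      presso[[cohortName]] <- stage(paste0("presso:", cohortName),
        mrPresso(set, nSim = config$nSim, seed = config$seed))
    if (config$runDiagnostics && nInstruments(set) >= 2) {
      loo[[cohortName]] <- stage(paste0("leave_one_out:", cohortName),
                                 leaveOneOut(set))
      forest[[cohortName]] <- stage(paste0("forest:", cohortName),
                                    singleSnpForest(set))
    }
  }
  results <- do.call(rbind, allRes)
  rownames(results) <- NULL

  # fixed-effect meta-analysis of each method across cohorts
  if (length(config$cohorts) > 1 && !is.null(results)) {
    metaRows <- list()
    for (sn in unique(results$subset)) {
      for (m in unique(results$method)) {
        sel <- results$subset == sn & results$method == m
        if (sum(sel) < 2) next
        ests <- lapply(which(sel), function(i)
          newEstimate(m, results$beta[i], results$se[i], results$J[i]))
        me <- stage("meta", metaFixed(ests))
        metaRows[[paste(sn, m)]] <- cbind(
          data.frame(direction = config$label, cohort = "meta(fixed)",
                     subset = sn, stringsAsFactors = FALSE),
          estimateAsData(me))
      }
    }
    results <- rbind(results, do.call(rbind, metaRows))
    rownames(results) <- NULL
  }
  results <- applyTransform(results, config$transform)
  list(label = config$label, results = results, presso = presso,
       leaveOneOut = loo, forest = forest, dropped = droppedL,
       instruments = instruments)
}

#' Run the bi-directional analysis
#'
#' Runs [runDirection()] for the forward direction (biomarker exposure,
#' disease outcome) and, when supplied, the reverse direction (disease
#' liability exposure, biomarker outcome), returning both reports.
#'
#' @param forward,reverse \code{mrAnalysisConfig} objects; \code{reverse}
#'   may be NULL for a one-direction run.
#' @return list of class \code{mrReport} with elements \code{forward} and
#'   (optionally) \code{reverse}.
#' @export
runBidirectional <- function(forward, reverse = NULL) {
  out <- list(forward = runDirection(forward))
  if (!is.null(reverse)) out$reverse <- runDirection(reverse)
  class(out) <- "mrReport"
  out
}

pressoAsList <- function(x) {
  list(
    rss_observed = x@rssObserved, global_p = x@globalP,
    per_variant_p = as.list(x@perVariantP), outliers = x@outliers,
    beta_raw = as.list(estimateAsData(x@betaRaw)),
    beta_corrected = if (is.null(x@betaCorrected)) NULL else
      as.list(estimateAsData(x@betaCorrected)),
    distortion_coef = x@distortionCoef, distortion_p = x@distortionP,
    n_sim = x@nSim, seed = x@seed
  )
}

#' Write a report to disk
#'
#' Writes \code{results.tsv} (all estimates), \code{loo.tsv}
#' (leave-one-out rows), \code{presso.json} and \code{report.json} under
#' \code{dir}. Output is deterministic given the configuration seeds.
#'
#' @param report an \code{mrReport} from [runBidirectional()] or a single
#'   [runDirection()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
writeMRReport <- function(report, dir) {
  if (!inherits(report, "mrReport")) report <- structure(
    list(forward = report), class = "mrReport")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- Filter(Negate(is.null), report[c("forward", "reverse")])
  results <- do.call(rbind, lapply(dirs, `[[`, "results"))
  rownames(results) <- NULL
  write.table(results, file.path(dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  looAll <- list()
  for (d in dirs) for (cn in names(d$leaveOneOut))
    looAll[[paste(d$label, cn)]] <- cbind(
      data.frame(direction = d$label, cohort = cn,
                 stringsAsFactors = FALSE), d$leaveOneOut[[cn]])
  if (length(looAll)) {
    looDf <- do.call(rbind, looAll)
    rownames(looDf) <- NULL
    write.table(looDf, file.path(dir, "loo.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  pressoAll <- lapply(dirs, function(d) lapply(d$presso, pressoAsList))
  jsonlite::write_json(pressoAll, file.path(dir, "presso.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rep <- lapply(dirs, function(d) list(
    label = d$label, results = d$results,
    dropped = lapply(d$dropped, identity),
    presso = lapply(d$presso, pressoAsList)))
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
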