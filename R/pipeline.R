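# End-to-end orchestration: hygiene -> compliance exclusion ->
# standardization -> fitness LCSM -> per-ROI invariance ladder -> group
# mean-change and variance-in-change tests -> bivariate change-change models
# for ROI x interval cells passing both gates.

#' Pipeline configuration
#'
#' Exactly one of `simConfig` / `table` must be supplied.
#'
#' @param simConfig a [simConfig()] to generate data from (its seed is
#'   overridden by `seed`).
#' @param table an existing [StudyTable-class].
#' @param trainingLogs optional data.frame of per-participant logs (columns
#'   `participant_id`, `week`, `minutes`, `watts`) for compliance exclusion.
#' @param rois ROI tokens to analyse (default: all in the data).
#' @param alpha one-sided/two-sided significance level for change tests and
#'   invariance steps.
#' @param covariates covariate set added to sensitivity variants (empty =
#'   simpler models only).
#' @param complianceMode `"t1-retained"` (non-compliant participants keep
#'   occasion-1 rows, lose occasions 2-3) or `"fully-excluded"`.
#' @param watchWatts require non-decreasing wattage for exercisers.
#' @param fdr additionally report Benjamini-Hochberg adjusted group
#'   difference p-values across ROIs (an opt-in extension, not part of the
#'   reproduced analysis).
#' @param restarts optimization restarts per model fit.
#' @param seed integer seed controlling generation.
#' @param fitThresholds `c(rmsea = , cfi = )` acceptability screen; failures
#'   annotate, never abort.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simConfig = NULL, table = NULL,
                           trainingLogs = NULL, rois = NULL, alpha = 0.05,
                           covariates = character(),
                           complianceMode = c("t1-retained",
                                              "fully-excluded"),
                           watchWatts = TRUE, fdr = FALSE, restarts = 3L,
                           seed = 1L,
                           fitThresholds = c(rmsea = 0.08, cfi = 0.90)) {
  complianceMode <- match.arg(complianceMode)
  if (is.null(simConfig) == is.null(table))
    stop("supply exactly one of simConfig / table")
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically for a given configuration and seed: outlier
#' hygiene (univariate 4-SD screen, then Mahalanobis screen per variable),
#' ICV adjustment of VBM variables, compliance-based exclusion of occasions
#' 2-3, longitudinal standardization, the fitness LCSM with group tests and
#' percent change, then per ROI the factorial-invariance ladder; for
#' invariant ROIs, group differences in mean change and within-group
#' directional change tests per interval, variance-in-change boundary tests,
#' and - only for ROI x interval cells passing both the group-difference and
#' variance gates - bivariate change-change models (pooled, per group, and
#' the group-difference test on the coupling).  RMSEA/CFI threshold failures
#' are annotated per model.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `studyReport`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  alpha <- config$alpha
  if (!is.null(config$simConfig)) {
    sc <- config$simConfig
    sc$seed <- config$seed
    table <- simulateStudy(sc)
  } else table <- config$table
  rois <- config$rois
  if (is.null(rois)) {
    have <- unique(sub("\\.[A-Z]+$", "",
                       setdiff(unique(table@measurements$variable),
                               "VO2peak")))
    rois <- intersect(roiRoster(), have)
  }

  # --- hygiene (fixed order: univariate -> multivariate -> ICV -> ---------
  # compliance -> standardize)
  uni <- flagUnivariateOutliers(table)
  table <- uni$table
  mvReports <- list()
  for (v in c(unlist(lapply(rois, roiVariables)), "VO2peak")) {
    mv <- flagMultivariateOutliers(table, v)
    table <- mv$table
    mvReports[[v]] <- mv$report
  }
  part <- table@participants
  meas <- table@measurements
  for (roi in rois) {
    v <- paste0(roi, ".VBM")
    for (t in sort(unique(meas$occasion[meas$variable == v]))) {
      sel <- meas$variable == v & meas$occasion == t
      icv <- part$icv[match(meas$participant_id[sel], part$participant_id)]
      meas$value[sel] <- adjustICV(meas$value[sel], icv)
    }
  }
  table <- methods::initialize(table, measurements = meas)

  compliance <- NULL
  if (!is.null(config$trainingLogs)) {
    logs <- split(config$trainingLogs, config$trainingLogs$participant_id)
    recs <- lapply(logs, function(l) {
      grp <- part$group[match(l$participant_id[1], part$participant_id)]
      classifyCompliance(l, requireNondecreasingWatts =
                           config$watchWatts && identical(grp, "EG"))
    })
    compliance <- data.frame(
      participant_id = names(recs),
      compliant = vapply(recs, `[[`, TRUE, "compliant"),
      reasons = vapply(recs, function(r)
        paste(r$reasons, collapse = ";"), ""),
      stringsAsFactors = FALSE)
    bad <- compliance$participant_id[!compliance$compliant]
    m <- table@measurements
    dropRows <- m$participant_id %in% bad &
      (if (config$complianceMode == "t1-retained") m$occasion > 1L else TRUE)
    table <- methods::initialize(table,
                                 measurements = m[!dropRows, , drop = FALSE])
  }

  rawTable <- table  # raw-scale copy (for percent change)
  for (v in unique(table@measurements$variable))
    table <- stackStandardize(table, v)

  # --- fitness LCSM -------------------------------------------------------
  fitness <- analyseFitness(table, rawTable, alpha, config$restarts)

  # --- per-ROI analysis ---------------------------------------------------
  roiResults <- list()
  for (roi in rois) {
    roiResults[[roi]] <- tryCatch(
      analyseRoi(roi, table, alpha, config$restarts, config$fitThresholds),
      error = function(e) list(roi = roi, error = conditionMessage(e)))
  }

  if (config$fdr) {
    for (int in c("d21", "d32")) {
      ps <- vapply(roiResults, function(r)
        if (!is.null(r$changeTests)) r$changeTests[[int]]$groupDiff$p_one_sided
        else NA_real_, 0)
      adj <- stats::p.adjust(ps, method = "BH")
      for (i in seq_along(roiResults))
        if (!is.null(roiResults[[i]]$changeTests))
          roiResults[[i]]$changeTests[[int]]$p_fdr <- adj[[i]]
    }
  }

  # gate-logic exactness: no change-change result without both gates passed
  for (r in roiResults)
    if (!is.null(r$changeChange))
      for (int in names(r$changeChange))
        stopifnot(isTRUE(r$gates[[int]]$groupDiff),
                  isTRUE(r$gates[[int]]$variance))

  structure(list(hygiene = list(univariate = uni$report,
                                multivariate = mvReports),
                 compliance = compliance, fitness = fitness,
                 rois = roiResults, roiRoster = rois, alpha = alpha,
                 seed = config$seed),
            class = "studyReport")
}

analyseFitness <- function(table, rawTable, alpha, restarts) {
  model <- buildUnivariateLCSM()
  fit <- fitModel(model, table, restarts = restarts)
  tests <- list()
  for (grp in c("ACG", "EG")) {
    child <- fitModel(fixChangeMean(model, "dfit", grp) , table,
                      restarts = restarts, se = FALSE, indices = FALSE)
    tests[[grp]] <- lrTest(fit, child,
                           direction = if (grp == "EG") "positive"
                           else "negative",
                           estimate = fit@estimates[paste0("mu_dfit_", grp)])
  }
  eq <- fitModel(equateChangeMean(model, "dfit"), table,
                 restarts = restarts, se = FALSE, indices = FALSE)
  groupDiff <- lrTest(fit, eq, direction = "positive",
                      estimate = unname(fit@estimates["mu_dfit_EG"] -
                                          fit@estimates["mu_dfit_ACG"]))
  rawFit <- fitModel(model, rawTable, restarts = restarts)
  pct <- lapply(c(ACG = "ACG", EG = "EG"), function(grp)
    percentChange(rawFit, paste0("mu_f1_", grp), paste0("mu_dfit_", grp)))
  list(fit = fit, withinGroup = tests, groupDiff = groupDiff,
       rawFit = rawFit, percentChange = pct)
}

fitScreen <- function(fit, thresholds) {
  warns <- character(0)
  if (is.finite(fit@rmsea) && fit@rmsea >= thresholds[["rmsea"]])
    warns <- c(warns, sprintf("RMSEA %.3f above threshold", fit@rmsea))
  if (is.finite(fit@cfi) && fit@cfi <= thresholds[["cfi"]])
    warns <- c(warns, sprintf("CFI %.3f below threshold", fit@cfi))
  warns
}

analyseRoi <- function(roi, table, alpha, restarts, thresholds) {
  inv <- invarianceLadder(roi, table, alpha = alpha, restarts = restarts)
  out <- list(roi = roi, invariance = inv)
  if (!inv$invariant) return(out)

  model <- buildIntegrityLCSM(roi)
  fit <- fitModel(model, table, restarts = restarts)
  out$fit <- fit
  out$fitWarnings <- fitScreen(fit, thresholds)
  std <- fit@std
  ld <- std[std$matrix == "A" & grepl("^l_", std$label) &
              std$group == "ACG", c("label", "estimate", "std")]
  # VBM is the fixed reference indicator: standardize its unit loading
  imp <- impliedMoments(fit@model, fit@estimates, full = TRUE)
  C <- imp$ACG$cov_full
  vbm1 <- paste0(roi, ".VBM_T1")
  loadings <- rbind(
    data.frame(label = "l_VBM_t1", estimate = 1,
               std = sqrt(C["si1", "si1"] / C[vbm1, vbm1])),
    ld)
  loadings$wald_p <- vapply(loadings$label, function(lb) {
    if (!lb %in% names(fit@estimates)) return(NA_real_)
    dirn <- if (grepl("MD", lb)) "negative" else "positive"
    tryCatch(waldLoadingTest(fit, lb, dirn), error = function(e) NA_real_)
  }, 0)
  out$loadings <- loadings

  out$changeTests <- list()
  out$gates <- list()
  for (int in c("d21", "d32")) {
    eq <- fitModel(equateChangeMean(model, int), table, restarts = restarts,
                   se = FALSE, indices = FALSE)
    gd <- lrTest(fit, eq, direction = "positive",
                 estimate = unname(fit@estimates[paste0("mu_", int, "_EG")] -
                                     fit@estimates[paste0("mu_", int,
                                                          "_ACG")]))
    within <- lapply(c(ACG = "ACG", EG = "EG"), function(grp) {
      child <- fitModel(fixChangeMean(model, int, grp), table,
                        restarts = restarts, se = FALSE, indices = FALSE)
      lrTest(fit, child,
             direction = if (grp == "EG") "positive" else "negative",
             estimate = fit@estimates[paste0("mu_", int, "_", grp)])
    })
    novar <- fitModel(fixChangeVariance(model, int), table,
                      restarts = restarts, se = FALSE, indices = FALSE)
    vt <- lrTest(fit, novar)
    # boundary heuristic: 50:50 mixture, p halved (flagged, not exact)
    vt$p_boundary <- vt$p_two_sided / 2
    vt$heuristic <- "chi-square mixture p = p/2"
    est <- fit@estimates
    out$changeTests[[int]] <- list(
      groupDiff = gd, within = within, varianceTest = vt,
      estimates = data.frame(
        group = c("ACG", "EG"),
        b0 = unname(est[paste0("mu_", int, "_", c("ACG", "EG"))]),
        se = unname(fit@se[paste0("mu_", int, "_", c("ACG", "EG"))])))
    out$gates[[int]] <- list(
      groupDiff = gd$p_one_sided < alpha,
      variance = vt$p_boundary < alpha)
  }

  # change-change stage for gated intervals
  cc <- list()
  for (int in c("d21", "d32")) {
    if (!(out$gates[[int]]$groupDiff && out$gates[[int]]$variance)) next
    cc[[int]] <- tryCatch(
      analyseChangeChange(roi, int, table, restarts, thresholds),
      error = function(e) list(error = conditionMessage(e)))
  }
  if (length(cc)) out$changeChange <- cc
  out
}

analyseChangeChange <- function(roi, int, table, restarts, thresholds) {
  cpl <- function(grp) paste0("c_dfit_", int, "_", grp)
  stdOf <- function(fit, grp) {
    std <- fit@std
    r <- std[std$label == cpl(grp), , drop = FALSE]
    if (nrow(r)) r$std[1] else NA_real_
  }
  # pooled single-group model
  pooledModel <- buildBivariateLCSM(roi, groups = "all")
  pooled <- fitModel(pooledModel, table, restarts = restarts)
  pooledTest <- lrTest(pooled,
                       fitModel(fixParam(pooledModel, cpl("all"), 0), table,
                                restarts = restarts, se = FALSE,
                                indices = FALSE),
                       direction = "positive",
                       estimate = pooled@estimates[cpl("all")])
  # two-group model
  model <- buildBivariateLCSM(roi)
  fit <- fitModel(model, table, restarts = restarts)
  perGroup <- lapply(c(ACG = "ACG", EG = "EG"), function(grp) {
    tst <- lrTest(fit, fitModel(fixParam(model, cpl(grp), 0), table,
                                restarts = restarts, se = FALSE,
                                indices = FALSE),
                  direction = "positive", estimate = fit@estimates[cpl(grp)])
    list(test = tst, phi = stdOf(fit, grp))
  })
  eqModel <- setParamLabel(model, cpl("EG"), cpl("ACG"))
  gd <- lrTest(fit, fitModel(eqModel, table, restarts = restarts,
                             se = FALSE, indices = FALSE),
               direction = "positive",
               estimate = unname(fit@estimates[cpl("EG")] -
                                   fit@estimates[cpl("ACG")]))
  list(pooled = list(fit = pooled, test = pooledTest,
                     phi = stdOf(pooled, "all"),
                     fitWarnings = fitScreen(pooled, thresholds)),
       perGroup = perGroup, groupDiff = gd,
       fitWarnings = fitScreen(fit, thresholds))
}

#' Percent change with delta-method standard error
#'
#' `100 * delta-mean / baseline-mean`, with the standard error propagated to
#' first order through the joint sampling covariance of the two mean
#' estimates.
#'
#' @param fit a converged [ramFit-class] with standard errors.
#' @param baselineLabel,deltaLabel labels of the baseline and change means.
#' @return list with `percent` and `se`.
#' @export
percentChange <- function(fit, baselineLabel, deltaLabel) {
  b <- unname(fit@estimates[baselineLabel])
  d <- unname(fit@estimates[deltaLabel])
  if (!is.finite(b) || abs(b) < 1e-8)
    stop("baseline mean too close to zero for percent change")
  V <- fit@vcov[c(baselineLabel, deltaLabel), c(baselineLabel, deltaLabel)]
  grad <- c(-100 * d / b^2, 100 / b)
  list(percent = 100 * d / b,
       se = sqrt(drop(t(grad) %*% V %*% grad)))
}

#' @export
print.studyReport <- function(x, ...) {
  cat("studyReport:", length(x$rois), "ROI(s), alpha =", x$alpha, "\n")
  inv <- vapply(x$rois, function(r)
    isTRUE(r$invariance$invariant), TRUE)
  cat("  invariant ROIs:", sum(inv), "of", length(inv), "\n")
  cc <- names(Filter(function(r) !is.null(r$changeChange), x$rois))
  cat("  change-change stage:",
      if (length(cc)) paste(cc, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Render report tables
#'
#' Writes `invariance.csv` / `invariance.md` (per-ROI invariance ladder
#' delta chi-squares, standardized loadings, group-difference delta
#' chi-squares per interval; non-invariant ROIs carry dashes downstream),
#' `estimates.csv` (per ROI, group and interval: b0, SE, delta chi-square,
#' one-sided p), `fitness.csv`, and `report.json`.  Estimates are formatted
#' to 3 decimals and chi-squares to 2.
#'
#' @param report a `studyReport`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
renderTables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt3 <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
  fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  rows <- lapply(report$rois, function(r) {
    stepChi <- function(nm) {
      s <- r$invariance$steps[[nm]]
      if (is.null(s)) NA_real_ else s$delta_chisq
    }
    stdOf <- function(mod) {
      if (is.null(r$loadings)) return(NA_real_)
      i <- grep(paste0("^l_", mod, "_"), r$loadings$label)
      if (length(i)) r$loadings$std[i[1]] else NA_real_
    }
    gdChi <- function(int) {
      if (is.null(r$changeTests)) return(NA_real_)
      r$changeTests[[int]]$groupDiff$delta_chisq
    }
    data.frame(roi = r$roi,
               invariant = isTRUE(r$invariance$invariant),
               group_metric = stepChi("group-metric"),
               group_strict = stepChi("group-strict"),
               time_metric = stepChi("time-metric"),
               time_strict = stepChi("time-strict"),
               std_VBM = stdOf("VBM"), std_MT = stdOf("MT"),
               std_MD = stdOf("MD"),
               gd_chisq_d21 = gdChi("d21"), gd_chisq_d32 = gdChi("d32"),
               stringsAsFactors = FALSE)
  })
  invTab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(invTab, file.path(dir, "invariance.csv"),
                   row.names = FALSE)
  md <- c(paste("| ROI | invariant | group metric (df2) | group strict (df3)",
                "| time metric (df4) | time strict (df6) | VBM | MT | MD |",
                "group diff T1-T2 (df1) | group diff T2-T3 (df1) |"),
          paste(c("|", rep("---|", 11)), collapse = ""))
  for (i in seq_len(nrow(invTab)))
    md <- c(md, paste("|", invTab$roi[i], "|", invTab$invariant[i], "|",
                      paste(fmt2(unlist(invTab[i, 3:6])), collapse = " | "),
                      "|", paste(fmt3(unlist(invTab[i, 7:9])),
                                 collapse = " | "),
                      "|", paste(fmt2(unlist(invTab[i, 10:11])),
                                 collapse = " | "), "|"))
  writeLines(md, file.path(dir, "invariance.md"))

  est <- list()
  for (r in report$rois) {
    if (is.null(r$changeTests)) next
    for (int in names(r$changeTests)) {
      ct <- r$changeTests[[int]]
      for (i in 1:2)
        est[[length(est) + 1]] <- data.frame(
          roi = r$roi, interval = int, group = ct$estimates$group[i],
          b0 = ct$estimates$b0[i], se = ct$estimates$se[i],
          delta_chisq = ct$within[[ct$estimates$group[i]]]$delta_chisq,
          p_one_sided = ct$within[[ct$estimates$group[i]]]$p_one_sided,
          stringsAsFactors = FALSE)
    }
  }
  estTab <- if (length(est)) do.call(rbind, est) else
    data.frame(roi = character(0))
  if (nrow(estTab)) {
    estTab$b0 <- round(estTab$b0, 3); estTab$se <- round(estTab$se, 3)
    estTab$delta_chisq <- round(estTab$delta_chisq, 2)
    estTab$p_one_sided <- round(estTab$p_one_sided, 3)
  }
  utils::write.csv(estTab, file.path(dir, "estimates.csv"),
                   row.names = FALSE)

  fx <- report$fitness
  fitTab <- data.frame(
    group = c("ACG", "EG"),
    b0 = unname(fx$fit@estimates[c("mu_dfit_ACG", "mu_dfit_EG")]),
    se = unname(fx$fit@se[c("mu_dfit_ACG", "mu_dfit_EG")]),
    delta_chisq = c(fx$withinGroup$ACG$delta_chisq,
                    fx$withinGroup$EG$delta_chisq),
    p_one_sided = c(fx$withinGroup$ACG$p_one_sided,
                    fx$withinGroup$EG$p_one_sided),
    percent_change = c(fx$percentChange$ACG$percent,
                       fx$percentChange$EG$percent),
    percent_se = c(fx$percentChange$ACG$se, fx$percentChange$EG$se),
    stringsAsFactors = FALSE)
  utils::write.csv(fitTab, file.path(dir, "fitness.csv"), row.names = FALSE)

  json <- file.path(dir, "report.json")
  jsonlite::write_json(summarizeReport(report), json, auto_unbox = TRUE,
                       digits = 10)
  invisible(file.path(dir, c("invariance.csv", "invariance.md",
                             "estimates.csv", "fitness.csv", "report.json")))
}

# JSON-friendly numeric summary (drops S4 fit objects)
summarizeReport <- function(report) {
  list(
    alpha = report$alpha, seed = report$seed,
    hygiene = list(
      univariate_discarded = attr(report$hygiene$univariate,
                                  "cells_discarded"),
      multivariate_discarded = sum(vapply(report$hygiene$multivariate,
                                          function(r)
                                            attr(r, "cells_discarded"), 0))),
    fitness = list(
      b0 = as.list(report$fitness$fit@estimates[c("mu_dfit_ACG",
                                                  "mu_dfit_EG")]),
      groupDiff_chisq = report$fitness$groupDiff$delta_chisq,
      groupDiff_p = report$fitness$groupDiff$p_one_sided,
      percentChange = lapply(report$fitness$percentChange, function(p)
        list(percent = p$percent, se = p$se))),
    rois = lapply(report$rois, function(r) {
      out <- list(invariant = isTRUE(r$invariance$invariant),
                  failing_step = r$invariance$failing_step)
      if (!is.null(r$changeTests))
        out$changeTests <- lapply(r$changeTests, function(ct)
          list(groupDiff_chisq = ct$groupDiff$delta_chisq,
               groupDiff_p = ct$groupDiff$p_one_sided,
               variance_p = ct$varianceTest$p_boundary,
               b0 = as.list(stats::setNames(ct$estimates$b0,
                                            ct$estimates$group))))
      if (!is.null(r$changeChange))
        out$changeChange <- lapply(r$changeChange, function(cc)
          if (!is.null(cc$error)) list(error = cc$error) else
          list(pooled_phi = cc$pooled$phi,
               pooled_p = cc$pooled$test$p_one_sided,
               phi_ACG = cc$perGroup$ACG$phi, phi_EG = cc$perGroup$EG$phi,
               groupDiff_chisq = cc$groupDiff$delta_chisq,
               groupDiff_p = cc$groupDiff$p_one_sided))
      out
    }))
}
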