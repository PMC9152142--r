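# Likelihood-ratio machinery, directional tests, the factorial-invariance
# ladder, and simple descriptive group tests.

#' Likelihood-ratio test between nested fits
#'
#' `delta chi^2 = child(-2lnL) - parent(-2lnL)` with df the difference in
#' free-parameter counts; the child must be nested in the parent (its label
#' set a subset of the parent's, as produced by [setParamLabel()] /
#' [fixParam()]).  The two-sided p comes from the upper tail of the central
#' chi-square.  For df = 1 with a directional hypothesis, the one-sided p is
#' `p/2` when the free estimate's sign matches the hypothesized direction
#' and `1 - p/2` otherwise (positive change expected in exercisers, negative
#' in controls).
#'
#' @param parent fit of the freer model.
#' @param child fit of the constrained model.
#' @param direction `"positive"`, `"negative"` or `"none"`.
#' @param estimate the parent-model estimate whose sign is checked (required
#'   when a direction is given).
#' @return list of class `lrtResult`: `delta_chisq`, `delta_df`,
#'   `p_two_sided`, `p_one_sided` (when directional, df = 1),
#'   `direction`, `estimate_sign_matches`.
#' @export
lrTest <- function(parent, child, direction = c("none", "positive",
                                                "negative"),
                   estimate = NA_real_) {
  direction <- match.arg(direction)
  stopifnot(methods::is(parent, "ramFit"), methods::is(child, "ramFit"))
  if (!parent@converged || !child@converged)
    stop("both models must be converged for a likelihood-ratio test")
  pl <- paramLabels(parent@model); cl <- paramLabels(child@model)
  if (!all(cl %in% pl))
    stop("child not nested in parent: labels not a subset (",
         paste(setdiff(cl, pl), collapse = ", "), ")")
  ddf <- length(pl) - length(cl)
  if (ddf < 0) stop("child must not have more free parameters than parent")
  dchi <- child@minus2LL - parent@minus2LL
  if (dchi < -1e-6)
    stop("negative delta chi-square (", format(dchi),
         "): optimization failure, refit with more restarts")
  dchi <- max(dchi, 0)
  p2 <- if (ddf == 0) 1 else stats::pchisq(dchi, ddf, lower.tail = FALSE)
  out <- list(delta_chisq = dchi, delta_df = ddf, p_two_sided = p2,
              p_one_sided = NULL, direction = direction,
              estimate_sign_matches = NA)
  if (direction != "none") {
    if (ddf != 1) {
      warning("directional p only defined for df = 1; reporting two-sided")
    } else {
      if (is.na(estimate)) stop("directional test needs the free estimate")
      match_ <- (direction == "positive" && estimate > 0) ||
        (direction == "negative" && estimate < 0)
      out$estimate_sign_matches <- match_
      out$p_one_sided <- if (match_) p2 / 2 else 1 - p2 / 2
    }
  }
  structure(out, class = "lrtResult")
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("LRT: delta chi^2(%d) = %.3f, two-sided p = %.4f", x$delta_df,
              x$delta_chisq, x$p_two_sided))
  if (!is.null(x$p_one_sided))
    cat(sprintf(", one-sided (%s) p = %.4f", x$direction, x$p_one_sided))
  cat("\n")
  invisible(x)
}

#' Factorial-invariance ladder for one ROI
#'
#' Runs, in order: group invariance at occasion 1 (configural vs metric,
#' df = 2; metric vs strict, df = 3) on the two-group single-occasion factor
#' model, then time invariance with groups collapsed (pooled single-group
#' longitudinal model; configural vs metric, df = 4; metric vs strict,
#' df = 6).  Testing stops at the first step significant at the two-sided
#' `alpha`; the ROI is non-invariant if any step fails.
#'
#' @param roi ROI token.
#' @param data a hygiene-screened, standardized [StudyTable-class].
#' @param alpha two-sided significance level per step (0.05, uncorrected
#'   across ROIs).
#' @param restarts optimization restarts per fit.
#' @param stopAtFailure stop at the first significant step (the reported
#'   procedure); set `FALSE` to run all four steps regardless, e.g. for
#'   calibration studies of per-step rejection rates.
#' @return list of class `invarianceReport`: `roi`, `steps` (named list of
#'   `lrtResult`), `invariant`, `failing_step`.
#' @export
invarianceLadder <- function(roi, data, alpha = 0.05, restarts = 3L,
                             stopAtFailure = TRUE) {
  assertRoster(data, roiVariables(roi))
  steps <- list()
  failing <- NA_character_
  fitStep <- function(model) fitModel(model, data, restarts = restarts,
                                      se = FALSE, indices = FALSE)
  plan <- list(
    `group-metric` = function() {
      p <- fitStep(buildOccasionFactor(roi, level = "configural"))
      c_ <- fitStep(buildOccasionFactor(roi, level = "metric"))
      lrTest(p, c_)
    },
    `group-strict` = function() {
      p <- fitStep(buildOccasionFactor(roi, level = "metric"))
      c_ <- fitStep(buildOccasionFactor(roi, level = "strict"))
      lrTest(p, c_)
    },
    `time-metric` = function() {
      p <- fitStep(buildIntegrityLCSM(roi, groups = "all",
                                      invariance = "configural"))
      c_ <- fitStep(buildIntegrityLCSM(roi, groups = "all",
                                       invariance = "metric"))
      lrTest(p, c_)
    },
    `time-strict` = function() {
      p <- fitStep(buildIntegrityLCSM(roi, groups = "all",
                                      invariance = "metric"))
      c_ <- fitStep(buildIntegrityLCSM(roi, groups = "all",
                                       invariance = "strict"))
      lrTest(p, c_)
    })
  for (nm in names(plan)) {
    res <- tryCatch(plan[[nm]](), error = function(e)
      stop("invariance step '", nm, "' for ", roi, " failed: ",
           conditionMessage(e), call. = FALSE))
    steps[[nm]] <- res
    if (res$p_two_sided < alpha) {
      if (is.na(failing)) failing <- nm
      if (stopAtFailure) break
    }
  }
  structure(list(roi = roi, steps = steps, invariant = is.na(failing),
                 failing_step = failing, alpha = alpha),
            class = "invarianceReport")
}

#' @export
print.invarianceReport <- function(x, ...) {
  cat(sprintf("invariance ladder for %s: %s\n", x$roi,
              if (x$invariant) "invariant"
              else paste0("non-invariant (failed at ", x$failing_step, ")")))
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("  %-12s delta chi^2(%d) = %6.2f, p = %.4f\n", nm,
                s$delta_df, s$delta_chisq, s$p_two_sided))
  }
  invisible(x)
}

#' One-sided Wald test of a loading (or any labeled parameter)
#'
#' `z = estimate / SE`; the one-sided p is the standard-normal tail beyond
#' `z` in the hypothesized direction.
#'
#' @param fit a converged [ramFit-class] with standard errors.
#' @param label parameter label.
#' @param direction `"positive"` or `"negative"`.
#' @return one-sided p-value.
#' @export
waldLoadingTest <- function(fit, label, direction = c("positive",
                                                      "negative")) {
  direction <- match.arg(direction)
  stopifnot(label %in% names(fit@estimates))
  se <- fit@se[label]
  if (is.na(se)) stop("no standard error available for ", label)
  z <- unname(fit@estimates[label] / se)
  if (direction == "positive") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p (wraps `stats::t.test`).
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welchT <- function(groupA, groupB) {
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# --- nested-model helpers used by the pipeline -----------------------------

# equality-constrain the change mean of one interval (d21, d32 or dfit)
# across groups
equateChangeMean <- function(model, interval, groups = c("ACG", "EG")) {
  base <- paste0("mu_", interval)
  out <- model
  for (grp in groups[-1])
    out <- setParamLabel(out, paste0(base, "_", grp),
                         paste0(base, "_", groups[1]))
  out
}

# fix one group's change mean for an interval to zero
fixChangeMean <- function(model, interval, group) {
  fixParam(model, paste0("mu_", interval, "_", group), 0)
}

# boundary model: no individual differences in change for an interval
# (variance and every covariance involving that change fixed to 0)
fixChangeVariance <- function(model, interval = c("d21", "d32")) {
  interval <- match.arg(interval)
  other <- setdiff(c("d21", "d32"), interval)
  out <- model
  for (lb in paramLabels(model)) {
    if (grepl(paste0("^v_", interval, "_"), lb) ||
        grepl(paste0("^c_si1_", interval, "_"), lb) ||
        grepl(paste0("^c_", interval, "_", other, "_"), lb) ||
        grepl(paste0("^c_", other, "_", interval, "_"), lb) ||
        grepl(paste0("^c_dfit_", interval, "_"), lb) ||
        grepl(paste0("^c_f1_", interval, "_"), lb))
      out <- fixParam(out, lb, 0)
  }
  out
}
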