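#' @import methods
NULL

#' StudyTable: long-format observed measurements plus participant covariates
#'
#' The single ingestion container for observed (real or simulated) data.
#' `measurements` is a long data.frame with columns `participant_id`, `group`
#' (`"ACG"` or `"EG"`), `variable` (e.g. `"ACC_R.VBM"`, `"VO2peak"`),
#' `occasion` (1--3) and `value`.  Missing entries are absent rows, never
#' sentinel numbers.  `participants` carries one row per participant with
#' `participant_id`, `group`, `age` (years), `sex` (`"M"`/`"F"`),
#' `education_years` and `icv` (intracranial volume).
#'
#' @slot measurements long data.frame of observed values.
#' @slot participants per-participant covariate data.frame.
#' @slot latents simulated latent draws (empty for real data); kept so that
#'   generator self-consistency can be audited.
#' @export
setClass("StudyTable",
         representation(measurements = "data.frame",
                        participants = "data.frame",
                        latents = "data.frame"),
         prototype(latents = data.frame()))

setValidity("StudyTable", function(object) {
  m <- object@measurements
  need <- c("participant_id", "group", "variable", "occasion", "value")
  if (!all(need %in% names(m)))
    return(paste("measurements must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    if (anyNA(m$value))
      return("missing entries must be absent rows, not NA values")
    key <- paste(m$participant_id, m$variable, m$occasion)
    if (anyDuplicated(key))
      return("(participant, variable, occasion) must be unique")
    vo2 <- m$occasion[m$variable == "VO2peak"]
    if (length(vo2) && !all(vo2 %in% c(1L, 3L)))
      return("VO2peak occasions must be a subset of {1, 3}")
    if (!all(m$group %in% c("ACG", "EG")))
      return("group labels must be ACG or EG")
  }
  p <- object@participants
  pneed <- c("participant_id", "group", "age", "sex", "education_years", "icv")
  if (!all(pneed %in% names(p)))
    return(paste("participants must have columns:", paste(pneed, collapse = ", ")))
  TRUE
})

#' RAM-parameterized multigroup structural equation model
#'
#' Each group holds fixed numeric RAM matrices and parallel label matrices;
#' a label marks a free parameter, and the same label appearing in several
#' positions (within or across groups) imposes an equality constraint.
#' Convention: `A[i, j]` is the directed path from variable `j` to
#' variable `i`; `S` is the symmetric (co)variance matrix; `M` the
#' mean/intercept vector.  Manifest variables (those with data) are listed in
#' `manifest`; the remainder are latent.
#'
#' @slot groups named list; per group: `vars`, `manifest`, `A0`, `Albl`,
#'   `S0`, `Slbl`, `M0`, `Mlbl`.
#' @slot params data.frame with one row per unique free-parameter label:
#'   `label`, `start`, `lower`, `upper`, `sign` (hypothesized direction,
#'   `"positive"`, `"negative"` or `NA`).
#' @export
setClass("ramModel",
         representation(groups = "list", params = "data.frame"))

setValidity("ramModel", function(object) {
  for (gname in names(object@groups)) {
    g <- object@groups[[gname]]
    nv <- length(g$vars)
    for (nm in c("A0", "S0")) if (!all(dim(g[[nm]]) == nv))
      return(sprintf("group %s: %s has wrong dimension", gname, nm))
    if (!isTRUE(all.equal(g$S0, t(g$S0))))
      return(sprintf("group %s: S0 not symmetric", gname))
    if (!identical(g$Slbl, t(g$Slbl)))
      return(sprintf("group %s: S labels not symmetric", gname))
    if (!all(g$manifest %in% g$vars))
      return(sprintf("group %s: manifest not subset of vars", gname))
  }
  lbls <- unlist(lapply(object@groups, function(g)
    c(g$Albl, g$Slbl, g$Mlbl)), use.names = FALSE)
  lbls <- unique(lbls[!is.na(lbls)])
  if (!setequal(lbls, object@params$label))
    return("params table out of step with labels used in matrices")
  TRUE
})

#' Fitted RAM model
#'
#' @slot model the [ramModel-class] that was fitted.
#' @slot estimates,se named numeric vectors over free-parameter labels.
#' @slot vcov parameter covariance matrix (2 x inverse Hessian of -2lnL).
#' @slot minus2LL,satMinus2LL,indepMinus2LL -2 log-likelihoods of the fitted,
#'   saturated and independence models.
#' @slot chisq,df likelihood-ratio chi-square against the saturated model and
#'   its degrees of freedom.
#' @slot nTotal total number of cases across groups.
#' @slot rmsea,rmseaCI,cfi fit indices (RMSEA point + 95% CI, CFI).
#' @slot std standardized solution (data.frame).
#' @slot converged logical convergence status.
#' @slot diagnostics optimizer and numerical diagnostics.
#' @export
setClass("ramFit",
         representation(model = "ramModel", estimates = "numeric",
                        se = "numeric", vcov = "matrix",
                        minus2LL = "numeric", satMinus2LL = "numeric",
                        indepMinus2LL = "numeric",
                        chisq = "numeric", df = "integer", nTotal = "integer",
                        rmsea = "numeric", rmseaCI = "numeric", cfi = "numeric",
                        std = "data.frame", converged = "logical",
                        diagnostics = "list"))

#' @describeIn StudyTable-class number of measurement rows
#' @param object a `StudyTable`
#' @export
setMethod("show", "StudyTable", function(object) {
  m <- object@measurements
  cat("StudyTable:", nrow(object@participants), "participants,",
      nrow(m), "measurements\n")
  if (nrow(m)) {
    cat("  groups: ", paste(sprintf("%s (n=%d)",
        names(table(object@participants$group)),
        as.integer(table(object@participants$group))), collapse = ", "), "\n")
    cat("  variables:", length(unique(m$variable)),
        " occasions:", paste(sort(unique(m$occasion)), collapse = ","), "\n")
  }
  invisible(object)
})

#' @export
setMethod("show", "ramModel", function(object) {
  cat("ramModel:", length(object@groups), "group(s),",
      nrow(object@params), "free parameters\n")
  for (gname in names(object@groups)) {
    g <- object@groups[[gname]]
    cat(sprintf("  %s: %d manifest + %d latent variables\n", gname,
                length(g$manifest), length(g$vars) - length(g$manifest)))
  }
  invisible(object)
})

#' @export
setMethod("show", "ramFit", function(object) {
  cat(sprintf("ramFit: -2lnL = %.3f, chi^2(%d) = %.3f, converged: %s\n",
              object@minus2LL, object@df, object@chisq, object@converged))
  if (is.finite(object@rmsea))
    cat(sprintf("  RMSEA = %.3f [%.3f, %.3f], CFI = %.3f\n", object@rmsea,
                object@rmseaCI[1], object@rmseaCI[2], object@cfi))
  print(round(cbind(estimate = object@estimates, se = object@se), 4))
  invisible(object)
})

#' Accessors for study tables and fits
#'
#' `measurements()` and `participants()` return the two tables of a
#' [StudyTable-class]; `estimates()` the named coefficient vector of a
#' [ramFit-class].
#'
#' @param x object
#' @return the requested component.
#' @export
measurements <- function(x) x@measurements

#' @rdname measurements
#' @export
participants <- function(x) x@participants

#' @rdname measurements
#' @export
estimates <- function(x) x@estimates

#' @importFrom stats coef vcov logLik
#' @export
setMethod("coef", "ramFit", function(object, ...) object@estimates)

#' @export
setMethod("vcov", "ramFit", function(object, ...) object@vcov)

#' @export
setMethod("logLik", "ramFit", function(object, ...) {
  structure(-object@minus2LL / 2, df = nrow(object@model@params),
            class = "logLik")
})
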