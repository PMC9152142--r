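# Builders for the three model families: univariate fitness LCSM,
# multivariate integrity LCSM (one latent integrity factor per occasion
# measured by VBM/MT/MD), and the bivariate fitness-integrity LCSM.
#
# Identification: reference-indicator scaling with the VBM loading fixed to 1
# at every occasion (VBM loads positively everywhere, making MD loadings come
# out negative); factor variances free.  Indicator intercepts are held equal
# across occasions within indicator at every invariance level (with the VBM
# intercept fixed to 0) so latent change means stay interpretable; "metric"
# equates loadings and "strict" additionally equates residual variances
# across occasions/groups.  Within-modality cross-occasion residual
# covariances are constrained equal (one parameter per modality per group).

MODSTARTS <- list(loading = c(VBM = 1, MT = 0.5, MD = -0.8),
                  resid = 0.5, methodCov = 0.1, factorVar = 0.4,
                  changeVar = 0.02)

#' Univariate two-occasion latent change score model
#'
#' `x_3 = x_1 + delta` with unit fixed paths; free per group: mean and
#' variance of `x_1`, mean and variance of the pseudo-latent change `delta`,
#' and their covariance.  Exactly identified (df = 0) per group, so fit
#' indices are perfect by definition.
#'
#' @param variable variable token observed at both occasions (default
#'   `"VO2peak"`).
#' @param occasions the two occasions (default `c(1, 3)`).
#' @param groups group labels; use `"all"` for a pooled single-group model.
#' @return a [ramModel-class] with labels `mu_f1_<g>`, `v_f1_<g>`,
#'   `mu_dfit_<g>`, `v_dfit_<g>`, `c_f1_dfit_<g>`.
#' @export
buildUnivariateLCSM <- function(variable = "VO2peak", occasions = c(1L, 3L),
                                groups = c("ACG", "EG")) {
  stopifnot(length(occasions) == 2)
  x1 <- paste0(variable, "_T", occasions[1])
  x3 <- paste0(variable, "_T", occasions[2])
  gs <- list(); params <- list()
  for (grp in groups) {
    sfx <- paste0("_", grp)
    g <- newRamGroup(c(x1, x3, "dfit"), c(x1, x3))
    g <- setPath(g, x1, x3, 1)
    g <- setPath(g, "dfit", x3, 1)
    g <- setCov(g, x1, x1, paste0("v_f1", sfx))
    g <- setCov(g, "dfit", "dfit", paste0("v_dfit", sfx))
    g <- setCov(g, x1, "dfit", paste0("c_f1_dfit", sfx))
    g <- setMean(g, x1, paste0("mu_f1", sfx))
    g <- setMean(g, "dfit", paste0("mu_dfit", sfx))
    gs[[grp]] <- g
    params <- c(params, list(
      paramRow(paste0("v_f1", sfx), 1, lower = 1e-6),
      paramRow(paste0("v_dfit", sfx), 0.3, lower = 1e-6),
      paramRow(paste0("c_f1_dfit", sfx), 0),
      paramRow(paste0("mu_f1", sfx), 0),
      paramRow(paste0("mu_dfit", sfx), 0)))
  }
  ramModel(gs, do.call(rbind, params))
}

# measurement-part labels for loadings/residuals given invariance level; an
# equated parameter reuses the first occasion's label so that every
# constrained model's label set is a subset of its parent's (nesting by
# label inclusion, verified in lrTest)
measLabel <- function(base, mod, t, grp, level, groupEqual) {
  tpart <- paste0("_t", if (level == "configural") t else 1)
  gpart <- if (groupEqual) "" else paste0("_", grp)
  paste0(base, "_", mod, tpart, gpart)
}

residLabel <- function(mod, t, grp, level, groupEqual) {
  tpart <- paste0("_t", if (level == "strict") 1 else t)
  gpart <- if (groupEqual) "" else paste0("_", grp)
  paste0("e_", mod, tpart, gpart)
}

# loading label used by strict/metric analysis models
loadingLabel <- function(mod, groupEqual = TRUE, grp = NULL) {
  paste0("l_", mod, "_t1", if (groupEqual) "" else paste0("_", grp))
}

addIntegrityStructure <- function(g, roi, grp, level, groupEqual,
                                  occasions = 3L) {
  mods <- modalityRoster()
  for (t in seq_len(occasions)) {
    si <- paste0("si", t)
    for (m in mods) {
      man <- paste0(roi, ".", m, "_T", t)
      lb <- if (m == "VBM") 1 else measLabel("l", m, t, grp, level, groupEqual)
      g <- setPath(g, si, man, lb)
      g <- setCov(g, man, man, residLabel(m, t, grp, level, groupEqual))
      # intercepts equal across occasions; VBM fixed 0 (reference)
      g <- setMean(g, man, if (m == "VBM") 0
                   else paste0("i_", m, if (groupEqual) "" else paste0("_", grp)))
    }
  }
  # latent change structure
  g <- setPath(g, "si1", "si2", 1); g <- setPath(g, "d21", "si2", 1)
  g <- setPath(g, "si2", "si3", 1); g <- setPath(g, "d32", "si3", 1)
  sfx <- paste0("_", grp)
  g <- setCov(g, "si1", "si1", paste0("v_si1", sfx))
  g <- setCov(g, "d21", "d21", paste0("v_d21", sfx))
  g <- setCov(g, "d32", "d32", paste0("v_d32", sfx))
  g <- setCov(g, "si1", "d21", paste0("c_si1_d21", sfx))
  g <- setCov(g, "si1", "d32", paste0("c_si1_d32", sfx))
  g <- setCov(g, "d21", "d32", paste0("c_d21_d32", sfx))
  g <- setMean(g, "si1", paste0("mu_si1", sfx))
  g <- setMean(g, "d21", paste0("mu_d21", sfx))
  g <- setMean(g, "d32", paste0("mu_d32", sfx))
  # within-modality cross-occasion residual covariances, equal per modality
  for (m in mods) {
    mc <- paste0("mc_", m, sfx)
    for (i in 1:(occasions - 1)) for (j in (i + 1):occasions)
      g <- setCov(g, paste0(roi, ".", m, "_T", i),
                  paste0(roi, ".", m, "_T", j), mc)
  }
  g
}

integrityParams <- function(roi, grp, level, groupEqual, occasions = 3L) {
  mods <- modalityRoster()
  sfx <- paste0("_", grp)
  params <- list(
    paramRow(paste0("v_si1", sfx), MODSTARTS$factorVar, lower = 1e-6),
    paramRow(paste0("v_d21", sfx), MODSTARTS$changeVar, lower = 1e-6),
    paramRow(paste0("v_d32", sfx), MODSTARTS$changeVar, lower = 1e-6),
    paramRow(paste0("c_si1_d21", sfx), 0),
    paramRow(paste0("c_si1_d32", sfx), 0),
    paramRow(paste0("c_d21_d32", sfx), 0),
    paramRow(paste0("mu_si1", sfx), 0),
    paramRow(paste0("mu_d21", sfx), 0, sign = if (grp == "EG") "positive"
             else if (grp == "ACG") "negative" else NA_character_),
    paramRow(paste0("mu_d32", sfx), 0, sign = if (grp == "EG") "positive"
             else if (grp == "ACG") "negative" else NA_character_))
  for (m in mods) {
    params[[length(params) + 1]] <- paramRow(paste0("mc_", m, sfx),
                                             MODSTARTS$methodCov)
    if (m != "VBM")
      params[[length(params) + 1]] <-
        paramRow(paste0("i_", m, if (groupEqual) "" else sfx), 0)
    for (t in seq_len(occasions)) {
      if (m != "VBM")
        params[[length(params) + 1]] <-
          paramRow(measLabel("l", m, t, grp, level, groupEqual),
                   MODSTARTS$loading[[m]])
      params[[length(params) + 1]] <-
        paramRow(residLabel(m, t, grp, level, groupEqual),
                 MODSTARTS$resid, lower = 1e-6)
    }
  }
  do.call(rbind, params)
}

#' Multivariate integrity latent change score model
#'
#' Per occasion `t`, a latent integrity factor loads on the ROI's VBM
#' (fixed 1), MT and MD indicators; the factors follow `si2 = si1 + d21`,
#' `si3 = si2 + d32` with unit paths.  Free per group: baseline factor
#' mean/variance, change means/variances, covariances among (baseline,
#' changes), indicator residual variances, one within-modality
#' cross-occasion residual covariance per modality, and MT/MD intercepts
#' (equal across occasions; VBM intercept fixed 0).
#'
#' @param roi ROI token (e.g. `"ACC_R"`).
#' @param groups group labels, or `"all"` for a pooled single-group model.
#' @param invariance `"strict"` (loadings and residual variances equal
#'   across occasions and, when `groupEqual`, groups), `"metric"` (loadings
#'   equal, residuals per occasion) or `"configural"` (both per occasion).
#' @param groupEqual share measurement parameters (loadings, residuals,
#'   intercepts) across groups; latent means/variances stay group-specific.
#' @return a [ramModel-class].
#' @export
buildIntegrityLCSM <- function(roi, groups = c("ACG", "EG"),
                               invariance = c("strict", "metric",
                                              "configural"),
                               groupEqual = length(groups) > 1) {
  invariance <- match.arg(invariance)
  mans <- as.vector(t(outer(roiVariables(roi), paste0("_T", 1:3), paste0)))
  lats <- c("si1", "si2", "si3", "d21", "d32")
  gs <- list(); params <- list()
  for (grp in groups) {
    g <- newRamGroup(c(mans, lats), mans)
    g <- addIntegrityStructure(g, roi, grp, invariance, groupEqual)
    gs[[grp]] <- g
    params[[grp]] <- integrityParams(roi, grp, invariance, groupEqual)
  }
  ramModel(gs, unique(do.call(rbind, params)))
}

#' Single-occasion integrity factor model (invariance ladder, group steps)
#'
#' One-factor model of the three modality indicators at one occasion, per
#' group, with free manifest means.  `level = "configural"` frees loadings
#' and residuals per group; `"metric"` equates loadings across groups
#' (2 constraints); `"strict"` additionally equates residual variances
#' (3 more).
#'
#' @param roi ROI token.
#' @param occasion measurement occasion (default 1).
#' @param groups group labels.
#' @param level invariance level across groups.
#' @return a [ramModel-class].
#' @export
buildOccasionFactor <- function(roi, occasion = 1L, groups = c("ACG", "EG"),
                                level = c("configural", "metric", "strict")) {
  level <- match.arg(level)
  mods <- modalityRoster()
  mans <- paste0(roi, ".", mods, "_T", occasion)
  gs <- list(); params <- list()
  for (grp in groups) {
    shareL <- level %in% c("metric", "strict")
    shareE <- level == "strict"
    g <- newRamGroup(c(mans, "si"), mans)
    g <- setCov(g, "si", "si", paste0("v_si_", grp))
    params <- c(params, list(paramRow(paste0("v_si_", grp),
                                      MODSTARTS$factorVar, lower = 1e-6)))
    for (i in seq_along(mods)) {
      m <- mods[i]
      lb <- if (m == "VBM") 1 else
        paste0("l_", m, "_", if (shareL) groups[1] else grp)
      eb <- paste0("e_", m, "_", if (shareE) groups[1] else grp)
      mb <- paste0("m_", m, "_", grp)
      g <- setPath(g, "si", mans[i], lb)
      g <- setCov(g, mans[i], mans[i], eb)
      g <- setMean(g, mans[i], mb)
      if (m != "VBM")
        params <- c(params, list(paramRow(lb, MODSTARTS$loading[[m]])))
      params <- c(params, list(paramRow(eb, MODSTARTS$resid, lower = 1e-6),
                               paramRow(mb, 0)))
    }
    gs[[grp]] <- g
  }
  ramModel(gs, unique(do.call(rbind, params)))
}

#' Bivariate fitness-integrity latent change score model
#'
#' Union of [buildIntegrityLCSM()] and [buildUnivariateLCSM()] structures
#' plus free covariances `(dfit, d21)`, `(dfit, d32)`, `(fit1, si1)`,
#' `(fit1, d21)`, `(fit1, d32)`, `(dfit, si1)` per group; the standardized
#' `(dfit, d21)` covariance is the change-change coupling phi.
#'
#' @inheritParams buildIntegrityLCSM
#' @param fitnessVariable fitness variable observed at occasions 1 and 3.
#' @return a [ramModel-class].
#' @export
buildBivariateLCSM <- function(roi, groups = c("ACG", "EG"),
                               invariance = "strict",
                               groupEqual = length(groups) > 1,
                               fitnessVariable = "VO2peak") {
  x1 <- paste0(fitnessVariable, "_T1")
  x3 <- paste0(fitnessVariable, "_T3")
  mans <- c(as.vector(t(outer(roiVariables(roi), paste0("_T", 1:3),
                              paste0))), x1, x3)
  lats <- c("si1", "si2", "si3", "d21", "d32", "dfit")
  gs <- list(); params <- list()
  for (grp in groups) {
    sfx <- paste0("_", grp)
    g <- newRamGroup(c(mans, lats), mans)
    g <- addIntegrityStructure(g, roi, grp, invariance, groupEqual)
    g <- setPath(g, x1, x3, 1)
    g <- setPath(g, "dfit", x3, 1)
    g <- setCov(g, x1, x1, paste0("v_f1", sfx))
    g <- setCov(g, "dfit", "dfit", paste0("v_dfit", sfx))
    g <- setCov(g, x1, "dfit", paste0("c_f1_dfit", sfx))
    g <- setMean(g, x1, paste0("mu_f1", sfx))
    g <- setMean(g, "dfit", paste0("mu_dfit", sfx))
    g <- setCov(g, "dfit", "d21", paste0("c_dfit_d21", sfx))
    g <- setCov(g, "dfit", "d32", paste0("c_dfit_d32", sfx))
    g <- setCov(g, "dfit", "si1", paste0("c_dfit_si1", sfx))
    g <- setCov(g, x1, "si1", paste0("c_f1_si1", sfx))
    g <- setCov(g, x1, "d21", paste0("c_f1_d21", sfx))
    g <- setCov(g, x1, "d32", paste0("c_f1_d32", sfx))
    gs[[grp]] <- g
    params[[grp]] <- rbind(
      integrityParams(roi, grp, invariance, groupEqual),
      paramRow(paste0("v_f1", sfx), 1, lower = 1e-6),
      paramRow(paste0("v_dfit", sfx), 0.3, lower = 1e-6),
      paramRow(paste0("c_f1_dfit", sfx), 0),
      paramRow(paste0("mu_f1", sfx), 0),
      paramRow(paste0("mu_dfit", sfx), 0),
      paramRow(paste0("c_dfit_d21", sfx), 0, sign = "positive"),
      paramRow(paste0("c_dfit_d32", sfx), 0, sign = "positive"),
      paramRow(paste0("c_dfit_si1", sfx), 0),
      paramRow(paste0("c_f1_si1", sfx), 0),
      paramRow(paste0("c_f1_d21", sfx), 0),
      paramRow(paste0("c_f1_d32", sfx), 0))
  }
  ramModel(gs, unique(do.call(rbind, params)))
}

# grow a group's RAM matrices with new variables
extendGroup <- function(g, newvars, asManifest = TRUE) {
  vars <- c(g$vars, newvars)
  nv <- length(vars)
  grow <- function(M0, Mlbl) {
    A0 <- matrix(0, nv, nv, dimnames = list(vars, vars))
    Al <- matrix(NA_character_, nv, nv, dimnames = list(vars, vars))
    A0[seq_along(g$vars), seq_along(g$vars)] <- M0
    Al[seq_along(g$vars), seq_along(g$vars)] <- Mlbl
    list(A0, Al)
  }
  a <- grow(g$A0, g$Albl); s <- grow(g$S0, g$Slbl)
  g$A0 <- a[[1]]; g$Albl <- a[[2]]; g$S0 <- s[[1]]; g$Slbl <- s[[2]]
  g$M0 <- c(g$M0, stats::setNames(numeric(length(newvars)), newvars))
  g$Mlbl <- c(g$Mlbl, stats::setNames(rep(NA_character_, length(newvars)),
                                      newvars))
  g$vars <- vars
  if (asManifest) g$manifest <- c(g$manifest, newvars)
  g
}

#' Add demographic covariates to an integrity model
#'
#' Each covariate enters as an exogenous manifest with free mean and
#' variance, free pairwise covariances with the other covariates, and
#' directed regression paths to the baseline integrity factor and both
#' latent changes.  FIML handles covariate missingness.
#'
#' @param model a [ramModel-class] containing latents `si1`, `d21`, `d32`.
#' @param covariates subset of `c("age", "sex", "education_years")`.
#' @return the extended model.
#' @export
addCovariates <- function(model, covariates = c("age", "sex",
                                                "education_years")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  params <- list()
  for (gname in names(model@groups)) {
    g <- model@groups[[gname]]
    clash <- intersect(covariates, g$vars)
    if (length(clash)) stop("covariate name collision: ",
                            paste(clash, collapse = ", "))
    g <- extendGroup(g, covariates)
    sfx <- paste0("_", gname)
    for (cv in covariates) {
      g <- setMean(g, cv, paste0("m_", cv, sfx))
      g <- setCov(g, cv, cv, paste0("v_", cv, sfx))
      params <- c(params, list(
        paramRow(paste0("m_", cv, sfx), 0),
        paramRow(paste0("v_", cv, sfx), 1, lower = 1e-6)))
      for (target in c("si1", "d21", "d32")) {
        lb <- paste0("b_", cv, "_", target, sfx)
        g <- setPath(g, cv, target, lb)
        params <- c(params, list(paramRow(lb, 0)))
      }
    }
    if (length(covariates) > 1)
      for (i in 1:(length(covariates) - 1))
        for (j in (i + 1):length(covariates)) {
          lb <- paste0("c_", covariates[i], "_", covariates[j], sfx)
          g <- setCov(g, covariates[i], covariates[j], lb)
          params <- c(params, list(paramRow(lb, 0)))
        }
    model@groups[[gname]] <- g
  }
  ramModel(model@groups, rbind(model@params, do.call(rbind, params)))
}
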