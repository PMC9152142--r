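# Synthetic-data generator: study tables with the latent structure the
# analysis assumes (per-ROI integrity factor measured by three modalities,
# latent change across three occasions, fitness coupling, method effects,
# missingness and gross outliers), plus training logs.

#' Simulation configuration
#'
#' Population parameters driving [simulateStudy()].  Defaults emulate a
#' six-month at-home aerobic-exercise intervention in older adults with MRI
#' at three occasions: two groups (35 active controls, 40 exercisers), three
#' occasions, a per-ROI latent integrity factor (baseline SD 1) measured by
#' VBM (loading fixed 1), MT and MD (negative loading, strongest
#' standardized at about -0.86, VBM about 0.53, MT about 0.46 at baseline),
#' modality method effects shared across occasions, control-group latent
#' decline with exerciser maintenance, individual differences in change, and
#' positive fitness-change coupling in exercisers (VO2peak in mL/kg/min at
#' occasions 1 and 3).
#'
#' @param nPerGroup named integer vector `c(ACG = , EG = )`.
#' @param occasions number of measurement occasions (3).
#' @param rois character vector of ROI tokens to generate.
#' @param loadings raw factor loadings per modality (VBM, MT, MD).
#' @param residSD indicator residual SDs per modality.
#' @param methodSD SD of the participant-level method intercept per modality
#'   (realizes equal within-modality cross-occasion residual covariances).
#' @param intercepts indicator intercepts per modality (arbitrary units;
#'   longitudinal standardization removes them downstream).
#' @param baselineMean,baselineSD latent integrity baseline moments.
#' @param changeMeans list per group of `c(d21 = , d32 = )` latent change
#'   means per interval.
#' @param changeSDs latent change SDs `c(d21 = , d32 = )`.
#' @param latentCovs covariances `c(si1_d21, si1_d32, d21_d32)` among
#'   baseline and changes (default orthogonal).
#' @param fitnessBaseline `c(mean = , sd = )` of VO2peak at occasion 1.
#' @param fitnessChange list per group of `c(mean = , sd = )` for the
#'   fitness change from occasion 1 to 3.
#' @param coupling named correlation per group between fitness change and
#'   the first-interval integrity change (applied via a joint
#'   multivariate-normal draw, not post-hoc mixing).
#' @param icv `c(mean = , sd = )` intracranial volume (cm^3).
#' @param icvSlopeVBM slope of VBM indicators on centered ICV.
#' @param covariateEffects optional list per covariate (`age`, `sex`,
#'   `education_years`) of `c(si1 = , d21 = , d32 = )` latent shifts per
#'   standardized covariate unit (default none).
#' @param dropout per-occasion monotone dropout probability (occasions 2-3).
#' @param mcar additional cell-level missing-completely-at-random rate.
#' @param outlierRate,outlierSD gross-outlier contamination rate per MRI
#'   cell and magnitude in population-SD units.
#' @param roiOverrides named list: per ROI, a list of config fields to
#'   override (e.g. plant a group effect in one region).
#' @param seed integer seed; the same seed yields byte-identical output.
#' @return validated list of class `simConfig`.
#' @export
simConfig <- function(nPerGroup = c(ACG = 35L, EG = 40L),
                      occasions = 3L,
                      rois = roiRoster(),
                      loadings = c(VBM = 1, MT = 0.9, MD = -1),
                      residSD = c(VBM = 1.40, MT = 1.47, MD = 0.55),
                      methodSD = c(VBM = 0.8, MT = 0.9, MD = 0.25),
                      intercepts = c(VBM = 0.5, MT = 1.1, MD = 0.8),
                      baselineMean = 0, baselineSD = 1,
                      changeMeans = list(ACG = c(d21 = -0.04, d32 = -0.06),
                                         EG = c(d21 = 0, d32 = 0)),
                      changeSDs = c(d21 = 0.15, d32 = 0.15),
                      latentCovs = c(si1_d21 = 0, si1_d32 = 0, d21_d32 = 0),
                      fitnessBaseline = c(mean = 23, sd = 5.5),
                      fitnessChange = list(ACG = c(mean = 0.7, sd = 1.8),
                                           EG = c(mean = 2.3, sd = 1.8)),
                      coupling = c(ACG = 0.2, EG = 0.5),
                      icv = c(mean = 1500, sd = 140),
                      icvSlopeVBM = 4e-4,
                      covariateEffects = NULL,
                      dropout = 0.08, mcar = 0.02,
                      outlierRate = 0.002, outlierSD = 6,
                      roiOverrides = list(),
                      seed = 171L) {
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  sds <- c(cfg$residSD, cfg$methodSD, cfg$baselineSD, cfg$changeSDs,
           cfg$fitnessBaseline["sd"], cfg$icv["sd"],
           vapply(cfg$fitnessChange, `[[`, 0, "sd"))
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (any(abs(cfg$coupling) > 1)) stop("coupling must lie in [-1, 1]")
  if (any(cfg$dropout < 0 | cfg$dropout > 1) || cfg$mcar < 0 || cfg$mcar > 1)
    stop("missingness rates must lie in [0, 1]")
  for (grp in names(cfg$nPerGroup))
    for (roi in cfg$rois)
      latentSigma(resolveRoiConfig(cfg, roi), grp, roi)  # PSD check
  invisible(TRUE)
}

resolveRoiConfig <- function(cfg, roi) {
  ov <- cfg$roiOverrides[[roi]]
  if (is.null(ov)) return(cfg)
  utils::modifyList(cfg, ov)
}

# joint covariance of (si1, d21, d32, dfit) for one group; errors name the
# offending block if not positive semi-definite
latentSigma <- function(cfg, grp, roi = "<roi>") {
  sdd <- cfg$changeSDs
  sdf <- cfg$fitnessChange[[grp]]["sd"]
  S <- diag(c(cfg$baselineSD^2, sdd["d21"]^2, sdd["d32"]^2, sdf^2))
  dimnames(S) <- list(c("si1", "d21", "d32", "dfit"),
                      c("si1", "d21", "d32", "dfit"))
  S["si1", "d21"] <- S["d21", "si1"] <- cfg$latentCovs["si1_d21"]
  S["si1", "d32"] <- S["d32", "si1"] <- cfg$latentCovs["si1_d32"]
  S["d21", "d32"] <- S["d32", "d21"] <- cfg$latentCovs["d21_d32"]
  S["d21", "dfit"] <- S["dfit", "d21"] <-
    cfg$coupling[[grp]] * sdd["d21"] * sdf
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("latent covariance block not positive semi-definite for ", roi,
         " in group ", grp)
  S
}

# conditional MVN draw of (si1, d21, d32) given dfit values
conditionalLatents <- function(S, muX, dfit, muF) {
  Sxx <- S[1:3, 1:3]; Sxf <- S[1:3, 4]; vf <- S[4, 4]
  if (vf > 0) {
    condMu <- outer(dfit - muF, Sxf / vf, `*`)
    condMu <- sweep(condMu, 2, muX, `+`)
    condS <- Sxx - tcrossprod(Sxf) / vf
  } else {
    condMu <- matrix(muX, length(dfit), 3, byrow = TRUE)
    condS <- Sxx
  }
  condS <- (condS + t(condS)) / 2
  ev <- eigen(condS, symmetric = TRUE)
  R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
  condMu + matrix(stats::rnorm(length(dfit) * 3), ncol = 3) %*% R
}

#' Simulate a study table
#'
#' Draws, per participant: fitness baseline and change; per ROI, the latent
#' integrity trajectory `(eta1, eta2 = eta1 + d21, eta3 = eta2 + d32)` from a
#' joint multivariate normal including the configured fitness-change
#' coupling; modality method intercepts constant over occasions; then
#' manifest values `intercept + loading * eta_t + method + ICV term (VBM) +
#' iid residual`.  Monotone dropout, MCAR cell deletion and gross-outlier
#' contamination are applied last.  Reproducible from `config$seed`.
#'
#' @param config a [simConfig()].
#' @return a [StudyTable-class]; latent draws are kept in the `latents` slot
#'   for generator self-consistency checks.
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withr::local_seed(config$seed)
  groups <- names(config$nPerGroup)
  parts <- list(); meas <- list(); lat <- list()
  pid <- 0L
  for (grp in groups) {
    n <- config$nPerGroup[[grp]]
    ids <- sprintf("P%03d", pid + seq_len(n)); pid <- pid + n
    age <- round(stats::runif(n, 63, 76.9), 1)
    sex <- ifelse(stats::runif(n) < 0.45, "F", "M")
    edu <- round(pmin(pmax(stats::rnorm(n, 13.3, 3), 7), 18))
    icv <- stats::rnorm(n, config$icv["mean"], config$icv["sd"])
    parts[[grp]] <- data.frame(participant_id = ids, group = grp, age = age,
                               sex = sex, education_years = edu, icv = icv,
                               stringsAsFactors = FALSE)
    fit1 <- stats::rnorm(n, config$fitnessBaseline["mean"],
                         config$fitnessBaseline["sd"])
    fc <- config$fitnessChange[[grp]]
    dfit <- stats::rnorm(n, fc["mean"], fc["sd"])
    meas[[paste0(grp, ".vo2.1")]] <- data.frame(
      participant_id = ids, group = grp, variable = "VO2peak",
      occasion = 1L, value = fit1, stringsAsFactors = FALSE)
    meas[[paste0(grp, ".vo2.3")]] <- data.frame(
      participant_id = ids, group = grp, variable = "VO2peak",
      occasion = 3L, value = fit1 + dfit, stringsAsFactors = FALSE)
    lat[[paste0(grp, ".fit")]] <- data.frame(
      participant_id = ids, group = grp, roi = "VO2peak",
      fit1 = fit1, dfit = dfit, si1 = NA_real_, d21 = NA_real_,
      d32 = NA_real_, stringsAsFactors = FALSE)

    covShift <- matrix(0, n, 3)  # si1, d21, d32 shifts from covariates
    if (!is.null(config$covariateEffects)) {
      covs <- list(age = age, sex = as.numeric(sex == "F"),
                   education_years = edu)
      for (cv in names(config$covariateEffects)) {
        z <- covs[[cv]]
        z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
        b <- config$covariateEffects[[cv]]
        covShift <- covShift + outer(z, as.numeric(b[c("si1", "d21", "d32")]))
      }
    }

    for (roi in config$rois) {
      rc <- resolveRoiConfig(config, roi)
      S <- latentSigma(rc, grp, roi)
      cm <- rc$changeMeans[[grp]]
      muX <- c(rc$baselineMean, cm[["d21"]], cm[["d32"]])
      L <- conditionalLatents(S, muX, dfit, fc[["mean"]]) + covShift
      eta <- cbind(L[, 1], L[, 1] + L[, 2], L[, 1] + L[, 2] + L[, 3])
      lat[[paste0(grp, ".", roi)]] <- data.frame(
        participant_id = ids, group = grp, roi = roi, fit1 = fit1,
        dfit = dfit, si1 = L[, 1], d21 = L[, 2], d32 = L[, 3],
        stringsAsFactors = FALSE)
      meth <- vapply(modalityRoster(), function(m)
        stats::rnorm(n, 0, rc$methodSD[[m]]), numeric(n))
      for (m in modalityRoster()) {
        for (t in seq_len(rc$occasions)) {
          val <- rc$intercepts[[m]] + rc$loadings[[m]] * eta[, t] +
            meth[, m] + stats::rnorm(n, 0, rc$residSD[[m]])
          if (m == "VBM")
            val <- val + rc$icvSlopeVBM * (icv - rc$icv[["mean"]])
          meas[[paste(grp, roi, m, t, sep = ".")]] <- data.frame(
            participant_id = ids, group = grp,
            variable = paste0(roi, ".", m), occasion = as.integer(t),
            value = val, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, c(meas, list(make.row.names = FALSE)))
  part <- do.call(rbind, c(parts, list(make.row.names = FALSE)))

  # monotone dropout: once dropped, all later occasions are missing
  if (config$dropout > 0) {
    dropAt <- stats::setNames(rep(Inf, nrow(part)), part$participant_id)
    for (t in 2:max(3, config$occasions)) {
      u <- stats::runif(nrow(part))
      dropAt <- pmin(dropAt, ifelse(u < config$dropout & dropAt == Inf, t,
                                    Inf))
    }
    keep <- tab$occasion < dropAt[tab$participant_id] | tab$occasion == 1L
    tab <- tab[keep, , drop = FALSE]
  }
  if (config$mcar > 0)
    tab <- tab[stats::runif(nrow(tab)) >= config$mcar, , drop = FALSE]
  if (config$outlierRate > 0) {
    mri <- tab$variable != "VO2peak"
    popSD <- vapply(modalityRoster(), function(m)
      sqrt((config$loadings[[m]] * config$baselineSD)^2 +
             config$methodSD[[m]]^2 + config$residSD[[m]]^2), 0)
    hit <- which(mri & stats::runif(nrow(tab)) < config$outlierRate)
    if (length(hit)) {
      mod <- sub("^.*\\.", "", tab$variable[hit])
      sgn <- ifelse(stats::runif(length(hit)) < 0.5, -1, 1)
      tab$value[hit] <- tab$value[hit] +
        sgn * config$outlierSD * popSD[mod]
      outCells <- tab[hit, c("participant_id", "variable", "occasion")]
    }
  }
  st <- studyTable(tab, part, latents = do.call(rbind, c(lat,
    list(make.row.names = FALSE))))
  attr(st@measurements, "seed") <- config$seed
  if (exists("outCells", inherits = FALSE))
    attr(st@measurements, "outlier_cells") <- outCells
  st
}

#' Simulate weekly training logs
#'
#' Emits one 26-week log per requested compliance profile.  Profiles:
#' `compliant` (weekly minutes averaging well above 90 over the study, watts
#' non-decreasing), `low-minutes` (total below the 1890-minute criterion),
#' `long-pause` (a run of more than 2 consecutive zero-activity weeks),
#' `decreasing-watts` (negative wattage trend).
#'
#' @param config a [simConfig()] (supplies the seed).
#' @param profiles character vector of profile tokens (repeats allowed).
#' @return data.frame with `participant_id`, `profile`, `week`, `minutes`,
#'   `watts`.
#' @export
simulateTrainingLogs <- function(config,
                                 profiles = c("compliant", "low-minutes",
                                              "long-pause",
                                              "decreasing-watts")) {
  known <- c("compliant", "low-minutes", "long-pause", "decreasing-watts")
  bad <- setdiff(profiles, known)
  if (length(bad)) stop("unknown compliance profile(s): ",
                        paste(bad, collapse = ", "))
  withr::local_seed(config$seed + 1L)
  weeks <- 1:26
  logs <- lapply(seq_along(profiles), function(i) {
    p <- profiles[i]
    minutes <- pmax(stats::rnorm(26, 140, 15), 95)
    watts <- cummax(67.9 + 1.5 * weeks + stats::rnorm(26, 0, 2))
    if (p == "low-minutes") minutes <- pmax(stats::rnorm(26, 55, 10), 0)
    if (p == "long-pause") minutes[12:14] <- 0
    if (p == "decreasing-watts")
      watts <- rev(cummax(rev(80 - 1.2 * weeks + stats::rnorm(26, 0, 2))))
    data.frame(participant_id = sprintf("L%02d", i), profile = p,
               week = weeks, minutes = minutes, watts = watts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(logs, list(make.row.names = FALSE)))
}

#' Serialize a simulation configuration as YAML
#'
#' @param config a [simConfig()].
#' @param path file path; read back with `readSimConfig()`.
#' @return the path (write) or a `simConfig` (read).
#' @export
writeSimConfig <- function(config, path) {
  asMap <- function(x) {
    if (is.list(x)) lapply(x, asMap)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(asMap(unclass(config)), path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  # scalar maps come back as named lists; restore named vectors except for
  # the fields that are genuinely nested lists
  nested <- c("changeMeans", "fitnessChange", "covariateEffects",
              "roiOverrides")
  unmap <- function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)))
      unlist(x)
    else if (is.list(x)) lapply(x, unmap)
    else x
  }
  args <- raw
  for (f in setdiff(names(args), nested)) args[[f]] <- unmap(args[[f]])
  for (f in intersect(c("changeMeans", "fitnessChange"), names(args)))
    args[[f]] <- lapply(args[[f]], unlist)
  if (!is.null(args$covariateEffects))
    args$covariateEffects <- lapply(args$covariateEffects, unlist)
  if (length(args$roiOverrides))
    args$roiOverrides <- lapply(args$roiOverrides, function(o) {
      o2 <- lapply(o, unmap)
      for (f in intersect(c("changeMeans", "fitnessChange"), names(o2)))
        o2[[f]] <- lapply(o[[f]], unlist)
      o2
    })
  args$nPerGroup <- vapply(args$nPerGroup, as.integer, 1L)
  args$seed <- as.integer(args$seed)
  do.call(simConfig, args)
}
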