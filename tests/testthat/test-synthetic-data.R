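# Generator: determinism, degenerate cases, self-consistency against stored
# latent draws, population moments, missingness and contamination marginals.

smallConfig <- function(...) {
  simConfig(rois = "ACC_R", nPerGroup = c(ACG = 30L, EG = 30L), ...)
}

test_that("the same seed yields identical tables; config is validated", {
  cfg <- smallConfig(seed = 7L)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(measurements(a), measurements(b))
  expect_identical(participants(a), participants(b))
  expect_error(simConfig(changeSDs = c(d21 = -0.1, d32 = 0.1)), "SD")
  expect_error(simConfig(coupling = c(ACG = 0.2, EG = 1.4)), "coupling")
  # a latent covariance too large for the change SDs must name the block
  expect_error(smallConfig(latentCovs = c(si1_d21 = 0.9, si1_d32 = 0,
                                          d21_d32 = 0)),
               "positive semi-definite")
})

test_that("noise-free degenerate config reproduces the baseline latent draw", {
  cfg <- smallConfig(
    loadings = c(VBM = 1, MT = 1, MD = 1),
    residSD = c(VBM = 0, MT = 0, MD = 0),
    methodSD = c(VBM = 0, MT = 0, MD = 0),
    intercepts = c(VBM = 0, MT = 0, MD = 0),
    changeMeans = list(ACG = c(d21 = 0, d32 = 0), EG = c(d21 = 0, d32 = 0)),
    changeSDs = c(d21 = 0, d32 = 0), icvSlopeVBM = 0,
    dropout = 0, mcar = 0, outlierRate = 0, seed = 3L)
  st <- simulateStudy(cfg)
  m <- measurements(st)
  lat <- st@latents
  mri <- m[m$variable != "VO2peak", ]
  base <- lat$si1[match(paste(mri$participant_id, "ACC_R"),
                        paste(lat$participant_id, lat$roi))]
  expect_equal(mri$value, base, tolerance = 1e-12)
})

test_that("occasion-difference composite recovers the configured change mean", {
  cfg <- simConfig(rois = "ACC_R", nPerGroup = c(ACG = 2000L, EG = 100L),
                   changeMeans = list(ACG = c(d21 = -0.05, d32 = 0),
                                      EG = c(d21 = 0, d32 = 0)),
                   dropout = 0, mcar = 0, outlierRate = 0, seed = 17L)
  st <- simulateStudy(cfg)
  lat <- st@latents
  acg <- lat[lat$group == "ACG" & lat$roi == "ACC_R", ]
  # oracle: direct averaging of the generator's stored latent draws
  expect_lt(abs(mean(acg$d21) - (-0.05)),
            3 * sd(acg$d21) / sqrt(nrow(acg)))
  # and the observed VBM occasion difference (loading 1) agrees
  m <- measurements(st)
  w <- reshape(m[m$variable == "ACC_R.VBM" & m$group == "ACG",
                 c("participant_id", "occasion", "value")],
               idvar = "participant_id", timevar = "occasion",
               direction = "wide")
  dobs <- w[, 3] - w[, 2]
  expect_lt(abs(mean(dobs) - (-0.05)), 3 * sd(dobs) / sqrt(length(dobs)))
})

test_that("sample covariance of the 9 indicators matches the implied covariance", {
  cfg <- simConfig(rois = "HC_R", nPerGroup = c(ACG = 5000L, EG = 10L),
                   dropout = 0, mcar = 0, outlierRate = 0, icvSlopeVBM = 0,
                   seed = 23L)
  st <- simulateStudy(cfg)
  m <- measurements(st)
  m <- m[m$group == "ACG" & m$variable != "VO2peak", ]
  m$col <- paste0(m$variable, "_T", m$occasion)
  w <- reshape(m[, c("participant_id", "col", "value")],
               idvar = "participant_id", timevar = "col",
               direction = "wide")
  X <- as.matrix(w[, -1])
  colnames(X) <- sub("^value\\.", "", colnames(X))
  S <- cov(X)
  # implied covariance from config: loadings x latent cov + method + resid
  lam <- cfg$loadings; mods <- modalityRoster()
  latC <- matrix(cfg$baselineSD^2, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    # cov(eta_i, eta_j) with orthogonal changes: var(si1) + shared change vars
    extra <- 0
    if (i >= 2 && j >= 2) extra <- extra + cfg$changeSDs["d21"]^2
    if (i >= 3 && j >= 3) extra <- extra + cfg$changeSDs["d32"]^2
    latC[i, j] <- cfg$baselineSD^2 + extra
  }
  n <- sum(!is.na(X[, 1]))
  worst <- 0
  for (a in seq_len(9)) for (b in a:9) {
    ma <- mods[(a - 1) %/% 3 + 1]; ta <- (a - 1) %% 3 + 1
    mb <- mods[(b - 1) %/% 3 + 1]; tb <- (b - 1) %% 3 + 1
    imp <- lam[[ma]] * lam[[mb]] * latC[ta, tb] +
      (ma == mb) * cfg$methodSD[[ma]]^2 +
      (a == b) * cfg$residSD[[ma]]^2
    ca <- paste0("HC_R.", ma, "_T", ta); cb <- paste0("HC_R.", mb, "_T", tb)
    obs <- S[ca, cb]
    # Monte-Carlo SE of a covariance (normal theory)
    se <- sqrt((S[ca, ca] * S[cb, cb] + obs^2) / (n - 1))
    worst <- max(worst, abs(obs - imp) / se)
  }
  expect_lt(worst, 3)
})

test_that("missingness and contamination marginals sit in binomial bounds", {
  cfg <- simConfig(rois = c("ACC_R", "HC_L"),
                   nPerGroup = c(ACG = 400L, EG = 400L),
                   dropout = 0.08, mcar = 0.02, outlierRate = 0.002,
                   seed = 29L)
  st <- simulateStudy(cfg)
  m <- measurements(st)
  n <- 800
  # dropout by occasion 2: fraction of participants with no occasion-2 rows
  occ2 <- unique(m$participant_id[m$occasion == 2])
  dropped2 <- n - length(occ2)
  # occasion-2 cells also disappear via MCAR; a participant loses all 6 of
  # its occasion-2 MRI cells with probability ~ mcar^6, negligible, so
  # dropout dominates
  bounds <- qbinom(c(0.005, 0.995), n, cfg$dropout)
  expect_gte(dropped2, bounds[1])
  expect_lte(dropped2, bounds[2])
  # contamination count within binomial bounds of rate x cells
  out <- attr(m, "outlier_cells")
  cells <- nrow(m[m$variable != "VO2peak", ])
  bounds <- qbinom(c(0.005, 0.995), cells, cfg$outlierRate)
  expect_gte(nrow(out), bounds[1])
  expect_lte(nrow(out), bounds[2])
  # the 4-SD univariate screen catches the 6-SD contaminants
  scr <- flagUnivariateOutliers(st)
  key <- function(d) paste(d$participant_id, d$variable, d$occasion)
  expect_gt(mean(key(out) %in% key(scr$report)), 0.95)
})

test_that("training-log profiles round-trip through the compliance classifier", {
  cfg <- smallConfig(seed = 31L)
  expect_error(simulateTrainingLogs(cfg, "sauntering"), "unknown")
  logs <- simulateTrainingLogs(cfg, c("compliant", "low-minutes",
                                      "long-pause", "decreasing-watts"))
  recs <- lapply(split(logs, logs$participant_id), classifyCompliance,
                 requireNondecreasingWatts = TRUE)
  prof <- vapply(split(logs, logs$participant_id),
                 function(l) l$profile[1], "")
  compliant <- vapply(recs, `[[`, TRUE, "compliant")
  expect_identical(unname(compliant[prof == "compliant"]), TRUE)
  expect_identical(sum(!compliant), 3L)
  # violation patterns are exact
  lp <- logs[logs$profile == "long-pause", ]
  runs <- rle(lp$minutes == 0)
  expect_gte(max(runs$lengths[runs$values]), 3)
  cw <- recs[[names(prof)[prof == "compliant"]]]
  expect_gte(cw$total_minutes / 26, 90)
  expect_gte(cw$wattage_trend, 0)
})

test_that("study tables and configurations serialize round-trip", {
  cfg <- smallConfig(seed = 37L)
  st <- simulateStudy(cfg)
  d <- withr::local_tempdir()
  writeStudyTable(st, d)
  expect_true(startsWith(readLines(file.path(d, "measurements.csv"),
                                   n = 1), "# seed: 37"))
  back <- readStudyTable(d)
  expect_equal(measurements(back)$value, measurements(st)$value)
  expect_equal(participants(back)$icv, participants(st)$icv)
  yml <- file.path(d, "config.yaml")
  writeSimConfig(cfg, yml)
  cfg2 <- readSimConfig(yml)
  expect_equal(cfg2$changeMeans, cfg$changeMeans)
  expect_equal(cfg2$nPerGroup, cfg$nPerGroup)
  expect_identical(measurements(simulateStudy(cfg2)),
                   measurements(st))
})
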