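# Model-family builders: df accounting, constraint nesting, implied-moment
# structure, closed-form recovery on toy data, covariate blocks.

test_that("fitness LCSM is exactly identified and recovers mean differences", {
  m <- buildUnivariateLCSM()
  # 5 moments and 5 free parameters per group
  expect_equal(nrow(m@params), 10L)
  expect_equal(gm$momentCount(m), 10)
  # toy data: the change mean equals the arithmetic mean difference (the
  # occasion vectors must not be exactly collinear or the saturated MLE is
  # singular)
  x1 <- c(1, 2, 3, 5); x3 <- c(2, 4, 7, 5)
  tab <- tableFromOccasions(cbind(x1, x3),
                            variable = "VO2peak", occasions = c(1, 3),
                            groups = rep("ACG", 4))
  mono <- buildUnivariateLCSM(groups = "ACG")
  fit <- fitModel(mono, tab, restarts = 2, se = FALSE, indices = FALSE)
  expect_equal(unname(fit@estimates["mu_dfit_ACG"]), mean(x3) - mean(x1),
               tolerance = 1e-6)
  expect_equal(unname(fit@estimates["mu_f1_ACG"]), mean(x1),
               tolerance = 1e-6)
  # no-change data: both change mean and change variance go to the boundary
  tab0 <- tableFromOccasions(cbind(c(1, 2, 3, 5), c(1, 2, 3, 5)),
                             variable = "VO2peak", occasions = c(1, 3),
                             groups = rep("ACG", 4))
  fit0 <- fitModel(mono, tab0, restarts = 2, se = FALSE, indices = FALSE)
  expect_equal(unname(fit0@estimates["mu_dfit_ACG"]), 0, tolerance = 1e-5)
  expect_lt(unname(fit0@estimates["v_dfit_ACG"]), 1e-4)
})

test_that("invariance levels differ by the Table-2 df pattern", {
  # group ladder at occasion 1: configural -> metric frees 2, metric ->
  # strict frees 3
  nfree <- function(m) nrow(m@params)
  expect_equal(nfree(buildOccasionFactor("ACC_R", level = "configural")) -
                 nfree(buildOccasionFactor("ACC_R", level = "metric")), 2L)
  expect_equal(nfree(buildOccasionFactor("ACC_R", level = "metric")) -
                 nfree(buildOccasionFactor("ACC_R", level = "strict")), 3L)
  # time ladder (groups collapsed): configural -> metric 4, metric ->
  # strict 6
  expect_equal(nfree(buildIntegrityLCSM("ACC_R", groups = "all",
                                        invariance = "configural")) -
                 nfree(buildIntegrityLCSM("ACC_R", groups = "all",
                                          invariance = "metric")), 4L)
  expect_equal(nfree(buildIntegrityLCSM("ACC_R", groups = "all",
                                        invariance = "metric")) -
                 nfree(buildIntegrityLCSM("ACC_R", groups = "all",
                                          invariance = "strict")), 6L)
  # constraint-ladder nesting by label-set inclusion
  lab <- function(m) m@params$label
  expect_true(all(lab(buildIntegrityLCSM("ACC_R", groups = "all",
                                         invariance = "strict")) %in%
                    lab(buildIntegrityLCSM("ACC_R", groups = "all",
                                           invariance = "metric"))))
  expect_true(all(lab(buildIntegrityLCSM("ACC_R", groups = "all",
                                         invariance = "metric")) %in%
                    lab(buildIntegrityLCSM("ACC_R", groups = "all",
                                           invariance = "configural"))))
})

test_that("free parameters equal moments minus engine-reported df", {
  # independent enumeration for the full two-group strict model
  m <- buildIntegrityLCSM("ACC_R")
  perGroupLatent <- 9   # 3 means, 3 variances, 3 covariances
  perGroupMethod <- 3
  shared <- 2 + 3 + 2   # loadings, residuals, MT/MD intercepts
  expect_equal(nrow(m@params), 2 * (perGroupLatent + perGroupMethod) + shared)
  expect_equal(gm$momentCount(m), 2 * 9 * 12 / 2)
  # every level is identified (df >= 0)
  for (lev in c("configural", "metric", "strict")) {
    mm <- buildIntegrityLCSM("ACC_R", invariance = lev)
    expect_gte(gm$momentCount(mm) - nrow(mm@params), 0)
  }
})

test_that("within-modality cross-occasion covariances are implied equal", {
  m <- buildIntegrityLCSM("HC_R", groups = "all")
  vals <- setNames(m@params$start, m@params$label)
  vals["mc_VBM_all"] <- 0.17
  vals["v_d21_all"] <- 0; vals["v_d32_all"] <- 0
  imp <- impliedMoments(m, vals)
  S <- imp$all$sigma
  v <- function(t) paste0("HC_R.VBM_T", t)
  expect_equal(S[v(1), v(2)], S[v(1), v(3)], tolerance = 1e-12)
  expect_equal(S[v(1), v(2)], S[v(2), v(3)], tolerance = 1e-12)
})

test_that("bivariate model recovers planted coupling and the null", {
  couple <- function(rho, seed) {
    cfg <- simConfig(rois = "ACC_R", nPerGroup = c(ACG = 200L, EG = 200L),
                     changeSDs = c(d21 = 0.35, d32 = 0.2),
                     coupling = c(ACG = rho, EG = rho),
                     dropout = 0, mcar = 0, outlierRate = 0, seed = seed)
    st <- standardizeAll(simulateStudy(cfg))
    fit <- fitModel(buildBivariateLCSM("ACC_R"), st, restarts = 2)
    est <- unname(fit@estimates[c("c_dfit_d21_ACG", "c_dfit_d21_EG")])
    se <- unname(fit@se[c("c_dfit_d21_ACG", "c_dfit_d21_EG")])
    # population covariance on the standardized observed scale
    sdd <- 0.35; sdf <- cfg$fitnessChange$ACG[["sd"]]
    truthRaw <- rho * sdd * sdf
    m <- measurements(simulateStudy(cfg))
    list(est = est, se = se, truthRaw = truthRaw)
  }
  # null coupling: both group estimates within 3 SEs of 0
  r0 <- couple(0, 61)
  expect_true(all(abs(r0$est) < 3 * r0$se))
  # strong coupling: estimates significantly positive
  r5 <- couple(0.6, 62)
  expect_true(all(r5$est > 3 * r5$se))
})

test_that("covariate blocks add the documented parameters and recover effects", {
  base <- buildIntegrityLCSM("ACC_R")
  ext <- addCovariates(base, c("age", "sex", "education_years"))
  # per group: 3 means + 3 variances + 3 pairwise covariances + 9 paths
  expect_equal(nrow(ext@params) - nrow(base@params), 2L * 18L)
  expect_error(addCovariates(ext, "age"), "collision")

  # a covariate with zero effect has paths within 3 SEs of 0, and a planted
  # effect on the first-interval change is recovered
  cfg <- simConfig(rois = "ACC_R", nPerGroup = c(ACG = 250L, EG = 250L),
                   changeSDs = c(d21 = 0.3, d32 = 0.2),
                   covariateEffects = list(
                     age = c(si1 = 0, d21 = 0.3 * 0.3, d32 = 0)),
                   dropout = 0, mcar = 0, outlierRate = 0, seed = 71L)
  st <- standardizeAll(simulateStudy(cfg))
  m2 <- addCovariates(buildIntegrityLCSM("ACC_R"), c("age", "sex"))
  fit <- fitModel(m2, st, restarts = 2)
  expect_true(fit@converged)
  # pooled SD used by the longitudinal standardization of the VBM indicator
  raw <- measurements(simulateStudy(cfg))
  sVBM <- sd(raw$value[raw$variable == "ACC_R.VBM"])
  part <- participants(simulateStudy(cfg))
  for (grp in c("ACG", "EG")) {
    bs <- fit@estimates[paste0("b_sex_", c("si1", "d21", "d32"), "_", grp)]
    ses <- fit@se[paste0("b_sex_", c("si1", "d21", "d32"), "_", grp)]
    expect_true(all(abs(bs) < 3 * ses))
    # age shifts d21 by 0.3 change-SDs (= 0.09 latent units) per SD of age;
    # on the standardized VBM scale the regression per year of age is
    # 0.09 / (sd(age) * pooled SD)
    truth <- 0.09 / sd(part$age[part$group == grp]) / sVBM
    bAge <- unname(fit@estimates[paste0("b_age_d21_", grp)])
    seAge <- unname(fit@se[paste0("b_age_d21_", grp)])
    expect_lt(abs(bAge - truth), 3 * seAge)
  }
})

test_that("roster mismatches error early", {
  cfg <- simConfig(rois = "ACC_R", nPerGroup = c(ACG = 10L, EG = 10L),
                   seed = 5L)
  st <- simulateStudy(cfg)
  expect_error(invarianceLadder("HC_L", st), "lacks required variables")
})
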