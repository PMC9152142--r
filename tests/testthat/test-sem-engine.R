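# RAM algebra, FIML likelihood, optimization, fit indices, standardization.

test_that("implied moments reproduce closed forms", {
  # no paths: Sigma equals the manifest block of S, mu = 0
  g <- gm$newRamGroup(c("a_T1", "b_T1"), c("a_T1", "b_T1"))
  g <- gm$setCov(g, "a_T1", "a_T1", 2)
  g <- gm$setCov(g, "b_T1", "b_T1", 3)
  g <- gm$setCov(g, "a_T1", "b_T1", 0.5)
  m <- gm$ramModel(list(all = g), gm$paramRow("dummy", 0)[0, ])
  expect_error(impliedMoments(m), NA)
  imp <- impliedMoments(m, values = numeric(0))
  expect_equal(imp$all$sigma, matrix(c(2, .5, .5, 3), 2,
                                     dimnames = list(c("a_T1", "b_T1"),
                                                     c("a_T1", "b_T1"))))
  expect_equal(unname(imp$all$mu), c(0, 0))

  # one factor, loadings (1, l2, l3): Sigma_ij = l_i l_j psi + delta_ij th_i
  rf <- randomFactorModel(n = 10, seed = 2)
  vals <- c(l2 = 0.7, l3 = -1.1, th1 = 0.3, th2 = 0.4, th3 = 0.5,
            m1 = 0.1, m2 = -0.2, m3 = 0.3, psi = 0.9)
  imp <- impliedMoments(rf$model, vals)
  lam <- c(1, 0.7, -1.1); th <- c(0.3, 0.4, 0.5)
  expect_equal(unname(imp$all$sigma),
               outer(lam, lam) * 0.9 + diag(th), tolerance = 1e-12)
  expect_equal(unname(imp$all$mu), c(0.1, -0.2, 0.3))
  expect_lt(max(abs(imp$all$sigma - t(imp$all$sigma))), 1e-12)
})

test_that("LCSM-implied occasion-2 mean is intercept + (mu1 + muD) * loading", {
  m <- buildIntegrityLCSM("HC_R", groups = "all")
  vals <- setNames(m@params$start, m@params$label)
  vals["mu_si1_all"] <- 0.4; vals["mu_d21_all"] <- -0.1
  vals["i_MT_all"] <- 0.25
  lmt <- vals[["l_MT_t1_all"]]
  imp <- impliedMoments(m, vals)
  expect_equal(unname(imp$all$mu["HC_R.MT_T2"]),
               0.25 + (0.4 - 0.1) * lmt, tolerance = 1e-12)
  expect_equal(unname(imp$all$mu["HC_R.VBM_T2"]), 0.4 - 0.1,
               tolerance = 1e-12)
})

test_that("FIML matches the univariate closed form and is additive", {
  g <- gm$newRamGroup("x_T1", "x_T1")
  g <- gm$setCov(g, "x_T1", "x_T1", "s2")
  g <- gm$setMean(g, "x_T1", "mu")
  m <- gm$ramModel(list(all = g),
                   rbind(gm$paramRow("s2", 1, lower = 1e-6),
                         gm$paramRow("mu", 0)))
  tab1 <- tableFromMatrix(matrix(2.5, 1, 1, dimnames = list(NULL, "x")))
  v <- c(s2 = 1.7, mu = 0.4)
  expect_equal(fimlNeg2LL(m, tab1, v),
               log(2 * pi) + log(1.7) + (2.5 - 0.4)^2 / 1.7,
               tolerance = 1e-12)
  # duplicating every case doubles the deviance exactly
  tab2 <- tableFromMatrix(matrix(c(2.5, 2.5), 2, 1,
                                 dimnames = list(NULL, "x")))
  expect_equal(fimlNeg2LL(m, tab2, v), 2 * fimlNeg2LL(m, tab1, v),
               tolerance = 1e-12)
})

test_that("FIML equals case-by-case multivariate-normal evaluation", {
  rf <- randomFactorModel(n = 30, missing = TRUE, seed = 7)
  vals <- c(l2 = 0.8, l3 = -0.9, th1 = 0.5, th2 = 0.4, th3 = 0.6,
            m1 = 0, m2 = 0.2, m3 = -0.1, psi = 1.2)
  f <- fimlNeg2LL(rf$model, rf$table, vals)
  imp <- impliedMoments(rf$model, vals)
  mu <- imp$all$mu; Sig <- imp$all$sigma
  direct <- sum(apply(rf$X, 1, function(x) {
    o <- !is.na(x)
    xo <- x[o]; mo <- mu[o]; So <- Sig[o, o, drop = FALSE]
    sum(o) * log(2 * pi) + as.numeric(determinant(So)$modulus) +
      drop(t(xo - mo) %*% solve(So) %*% (xo - mo))
  }))
  expect_equal(f, direct, tolerance = 1e-10)
})

test_that("FIML deviance is invariant to variable and case reordering", {
  rf <- randomFactorModel(n = 25, missing = TRUE, seed = 11)
  vals <- c(l2 = 0.8, l3 = -0.9, th1 = 0.5, th2 = 0.4, th3 = 0.6,
            m1 = 0, m2 = 0.2, m3 = -0.1, psi = 1.2)
  base <- fimlNeg2LL(rf$model, rf$table, vals)
  meas <- measurements(rf$table)
  shuf <- meas[sample(nrow(meas)), ]
  tabS <- studyTable(shuf, participants(rf$table))
  expect_identical(fimlNeg2LL(rf$model, tabS, vals), base)
})

test_that("analytic gradient matches central finite differences", {
  rf <- randomFactorModel(n = 35, missing = TRUE, seed = 13)
  model <- gm$nameGroups(rf$model)
  wide <- gm$widenStudy(rf$table, model)
  cmp <- gm$compileModel(model, wide)
  set.seed(4)
  for (rep in 1:3) {
    th <- c(runif(2, -1, 1), runif(3, 0.3, 1), runif(3, -0.5, 0.5),
            runif(1, 0.4, 1.5))[c(1, 2, 3, 6, 4, 7, 5, 8, 9)]
    th <- th[seq_len(nrow(model@params))]
    # keep variances positive at their slots
    th[model@params$lower > -Inf] <- abs(th[model@params$lower > -Inf]) + .2
    r <- gm$.ram_fiml(th, unname(cmp), TRUE)
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-5; tp <- th; tm <- th
      tp[i] <- th[i] + h; tm[i] <- th[i] - h
      (gm$.ram_fiml(tp, unname(cmp), FALSE)$value -
         gm$.ram_fiml(tm, unname(cmp), FALSE)$value) / (2 * h)
    }, 0)
    expect_lt(max(abs(r$gradient - fd) / (abs(fd) + 1)), 1e-5)
  }
})

test_that("FIML equals complete-data ML on 20 random small models", {
  worst <- 0
  for (s in 1:20) {
    rf <- randomFactorModel(n = 30 + s, p = 3, missing = FALSE, seed = 100 + s)
    fit <- fitModel(rf$model, rf$table, restarts = 2, se = FALSE,
                    indices = FALSE)
    # complete-data ML: closed-form saturated deviance bound, and direct
    # density evaluation at the FIML optimum must agree with the optimum
    vals <- fit@estimates
    imp <- impliedMoments(rf$model, vals)
    mu <- imp$all$mu; Sig <- imp$all$sigma
    direct <- sum(apply(rf$X, 1, function(x)
      3 * log(2 * pi) + as.numeric(determinant(Sig)$modulus) +
        drop(t(x - mu) %*% solve(Sig) %*% (x - mu))))
    worst <- max(worst, abs(fit@minus2LL - direct))
  }
  expect_lt(worst, 1e-8)
})

test_that("saturated model recovers n-denominator sample moments with chisq 0", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  vars <- paste0(c("a", "b", "c"), "_T1")
  g <- gm$newRamGroup(vars, vars)
  params <- list()
  for (i in 1:3) {
    g <- gm$setMean(g, vars[i], paste0("m", i))
    params[[length(params) + 1]] <- gm$paramRow(paste0("m", i), 0)
    for (j in i:3) {
      lb <- paste0("s", i, j)
      g <- gm$setCov(g, vars[i], vars[j], lb)
      params[[length(params) + 1]] <-
        gm$paramRow(lb, if (i == j) 1 else 0,
                    lower = if (i == j) 1e-6 else -Inf)
    }
  }
  m <- gm$ramModel(list(all = g), do.call(rbind, params))
  fit <- fitModel(m, tableFromMatrix(X), restarts = 2)
  expect_equal(fit@chisq, 0, tolerance = 1e-5)
  expect_equal(unname(fit@estimates[c("m1", "m2", "m3")]),
               unname(colMeans(X)), tolerance = 1e-5)
  Smle <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(unname(fit@estimates[c("s11", "s22", "s33")]),
               unname(diag(Smle)), tolerance = 1e-4)
  expect_equal(unname(fit@estimates[c("s12", "s13", "s23")]),
               Smle[upper.tri(Smle)], tolerance = 1e-4)
})

test_that("chi-square is monotone under nested constraints", {
  set.seed(31)
  rf <- randomFactorModel(n = 60, seed = 31)
  parent <- fitModel(rf$model, rf$table, restarts = 2, se = FALSE)
  child <- fitModel(gm$fixParam(rf$model, "l2", 0), rf$table, restarts = 2,
                    se = FALSE)
  grandchild <- fitModel(gm$fixParam(gm$fixParam(rf$model, "l2", 0),
                                     "l3", 0),
                         rf$table, restarts = 2, se = FALSE)
  expect_gte(child@chisq, parent@chisq - 1e-6)
  expect_gte(grandchild@chisq, child@chisq - 1e-6)
})

test_that("fit indices reproduce arithmetic and noncentral round trips", {
  # perfect fit
  fi <- fitIndices(10, 10, 101, 300, 15)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # chisq = 2 df, df = 10, N = 101: RMSEA = sqrt(10/1000)
  fi <- fitIndices(20, 10, 101, 300, 15)
  expect_equal(fi$rmsea, sqrt(10 / 1000), tolerance = 1e-12)
  # CI bounds invert the noncentral chi-square CDF; the lower bound clips
  # to 0 while the central CDF at the observed chisq is below 0.975
  lamU <- fi$ci[2]^2 * 10 * 100
  expect_equal(pchisq(20, 10, ncp = lamU), 0.025, tolerance = 1e-6)
  expect_identical(fi$ci[1], 0)  # pchisq(20, 10) = 0.971 < 0.975
  fi2 <- fitIndices(30, 10, 101, 300, 15)
  lamL <- fi2$ci[1]^2 * 10 * 100
  expect_equal(pchisq(30, 10, ncp = lamL), 0.975, tolerance = 1e-6)
  lamU2 <- fi2$ci[2]^2 * 10 * 100
  expect_equal(pchisq(30, 10, ncp = lamU2), 0.025, tolerance = 1e-6)
  expect_lte(fi2$ci[1], fi2$rmsea)
  expect_gte(fi2$ci[2], fi2$rmsea)
})

test_that("standardized loading follows the closed form", {
  # lambda = 0.8, psi = 1, theta = 0.36: std = 0.8 / sqrt(0.64 + 0.36)
  rf <- randomFactorModel(n = 10, seed = 41)
  vals <- c(l2 = 0.8, l3 = 0.8, th1 = 0.36, th2 = 0.36, th3 = 0.36,
            m1 = 0, m2 = 0, m3 = 0, psi = 1)
  fit <- methods::new("ramFit", model = gm$nameGroups(rf$model),
                      estimates = vals,
                      se = vals * NA, vcov = matrix(NA_real_, 0, 0),
                      minus2LL = 0, satMinus2LL = 0, indepMinus2LL = 0,
                      chisq = 0, df = 0L, nTotal = 10L, rmsea = NA_real_,
                      rmseaCI = c(NA_real_, NA_real_), cfi = NA_real_,
                      std = data.frame(), converged = TRUE,
                      diagnostics = list())
  std <- standardizedSolution(fit)
  expect_equal(std$std[std$label == "l2"], 0.8, tolerance = 1e-12)
})

test_that("non-convergent or unidentified models are reported, not silent", {
  rf <- randomFactorModel(n = 20, seed = 51)
  # more parameters than moments: identification error
  m <- rf$model
  g <- m@groups$all
  g <- gm$setCov(g, "y1_T1", "y2_T1", "extra1")
  g <- gm$setCov(g, "y1_T1", "y3_T1", "extra2")
  g <- gm$setCov(g, "y2_T1", "y3_T1", "extra3")
  g <- gm$setPath(g, "f", "y1_T1", "l1f")
  m2 <- gm$ramModel(list(all = g),
                    rbind(m@params, gm$paramRow("extra1", 0),
                          gm$paramRow("extra2", 0), gm$paramRow("extra3", 0),
                          gm$paramRow("l1f", 1)))
  expect_error(fitModel(m2, rf$table), "not identified")
})
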