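# Model fitting: bounded quasi-Newton FIML optimization, standard errors,
# baseline models, fit indices, standardized solution.

# data-informed start values: manifest mean labels start at the observed
# variable mean, and variance labels of exogenous manifests (no incoming
# paths) at the observed variance; averaged over the positions sharing a
# label.  Keeps raw-scale covariates (age, ICV) from starting far off.
autoStart <- function(model, wide) {
  params <- model@params
  acc <- list()
  add <- function(lbl, val) {
    if (is.finite(val)) acc[[lbl]] <<- c(acc[[lbl]], val)
  }
  for (gname in names(model@groups)) {
    g <- model@groups[[gname]]
    X <- wide[[gname]]
    for (v in g$manifest) {
      x <- X[, v]; x <- x[!is.na(x)]
      if (length(x) < 2) next
      if (!is.na(g$Mlbl[v])) add(g$Mlbl[v], mean(x))
      exo <- all(g$A0[v, ] == 0) && all(is.na(g$Albl[v, ]))
      if (exo && !is.na(g$Slbl[v, v])) add(g$Slbl[v, v], stats::var(x))
    }
  }
  for (lbl in names(acc)) {
    i <- match(lbl, params$label)
    params$start[i] <- max(min(mean(acc[[lbl]]), params$upper[i]),
                           params$lower[i])
  }
  params
}

# deterministic jitter stream (LCG), independent of R's RNG
jitterStream <- function(seed, n) {
  out <- numeric(n)
  state <- (as.numeric(seed) + 1) %% 2147483647
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647 * 2 - 1
  }
  out
}

# optimize a compiled model with analytic gradients; multiple jittered
# restarts, stopping early once two consecutive attempts fail to improve
optimizeCompiled <- function(compiled, params, restarts = 5L,
                             factr = 1e5) {
  theta0 <- params$start
  lower <- params$lower
  upper <- params$upper
  cg <- unname(compiled)
  cache <- new.env(parent = emptyenv())
  evalAt <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return()
    r <- .ram_fiml(theta, cg, TRUE)
    cache$theta <- theta; cache$value <- r$value; cache$grad <- r$gradient
    cache$ok <- r$ok
    invisible()
  }
  fn <- function(theta) { evalAt(theta); cache$value }
  gr <- function(theta) { evalAt(theta); cache$grad }

  best <- NULL
  stall <- 0L
  for (a in seq_len(max(1L, restarts))) {
    th <- if (a == 1L) theta0 else {
      u <- jitterStream(a * 7919L, length(theta0))
      pmin(pmax(theta0 * (1 + 0.1 * u) + 0.05 * u * (theta0 == 0),
                lower + 1e-9 * (is.finite(lower))), upper)
    }
    opt <- tryCatch(
      stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 5000L, factr = factr)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-4) {
      stall <- 0L
      if (is.null(best) || opt$value < best$value) best <- opt
    } else {
      stall <- stall + 1L
      if (opt$value < best$value) best <- opt
      if (stall >= 2L && best$convergence == 0) break
    }
  }
  if (is.null(best))
    return(list(par = theta0, value = Inf, convergence = 99L))
  names(best$par) <- params$label
  best
}

#' Fit a RAM model by FIML
#'
#' Minimizes the FIML -2 log-likelihood by bounded quasi-Newton iteration
#' (L-BFGS-B with analytic RAM gradients) with jittered restarts.  Standard
#' errors come from the inverse of one-half the numerical Hessian of -2lnL at
#' the optimum.  Saturated (free means + covariances per group; closed form
#' for complete data, FIML-optimized under missingness) and independence
#' (free means + variances, zero covariances; closed form) reference models
#' supply the likelihood-ratio chi-square, RMSEA and CFI.
#'
#' @param model a [ramModel-class].
#' @param data a [StudyTable-class] (standardize upstream; see
#'   [stackStandardize()]).
#' @param start optional named start values overriding the model's.
#' @param restarts maximum optimization attempts (first from `start`, the
#'   rest jittered by 10%); attempts stop early once two in a row fail to
#'   improve a converged optimum.
#' @param se compute standard errors (numerical Hessian); disable in tight
#'   simulation loops where only the deviance is needed.
#' @param indices compute saturated/independence baselines and fit indices.
#' @return a [ramFit-class].
#' @export
fitModel <- function(model, data, start = NULL, restarts = 5L, se = TRUE,
                     indices = TRUE) {
  stopifnot(methods::is(model, "ramModel"))
  if (nrow(model@params) == 0) stop("model has no free parameters")
  model <- nameGroups(model)
  wide <- widenStudy(data, model)
  model@params <- autoStart(model, wide)
  if (!is.null(start)) {
    i <- match(names(start), model@params$label)
    stopifnot(!anyNA(i))
    model@params$start[i] <- unname(start)
  }
  nTotal <- sum(vapply(wide, nrow, 0L))
  npar <- nrow(model@params)
  df <- as.integer(round(momentCount(model) - npar))
  if (df < 0) stop("model not identified: df = ", df)

  compiled <- compileModel(model, wide)
  opt <- optimizeCompiled(compiled, model@params, restarts = restarts)
  converged <- is.finite(opt$value) && opt$convergence == 0
  est <- opt$par

  seVec <- rep(NA_real_, npar)
  names(seVec) <- model@params$label
  V <- matrix(NA_real_, npar, npar,
              dimnames = list(model@params$label, model@params$label))
  if (se && converged) {
    cg <- unname(compiled)
    H <- tryCatch(stats::optimHess(unname(est),
                    fn = function(th) .ram_fiml(th, cg, FALSE)$value,
                    gr = function(th) .ram_fiml(th, cg, TRUE)$gradient),
                  error = function(e) NULL)
    okH <- FALSE
    if (!is.null(H)) {
      ch <- tryCatch(chol(H / 2), error = function(e) NULL)
      if (!is.null(ch)) {
        V <- chol2inv(ch)
        dimnames(V) <- list(model@params$label, model@params$label)
        seVec <- sqrt(diag(V))
        okH <- TRUE
      }
    }
    if (!okH)
      warning("Hessian not positive definite; standard errors unavailable ",
              "(boundary or Heywood-adjacent solution)")
  }

  satLL <- NA_real_; indLL <- NA_real_; chisq <- NA_real_
  rmsea <- NA_real_; rmseaCI <- c(NA_real_, NA_real_); cfi <- NA_real_
  if (indices && converged) {
    satLL <- saturatedMinus2LL(wide)
    chisq <- opt$value - satLL
    if (chisq < 0) {
      if (chisq > -1e-6) {
        warning("tiny negative chi-square clipped to 0")
        chisq <- 0
      } else {
        # saturated fit under-converged: polish it before declaring failure
        satLL2 <- tryCatch(saturatedMinus2LLPolished(wide),
                           error = function(e) satLL)
        chisq <- opt$value - satLL2
        if (chisq < -1e-6)
          stop("negative chi-square (", format(chisq),
               "): optimization failure, refit with more restarts")
        satLL <- satLL2
        if (chisq < 0) chisq <- 0
      }
    }
    indLL <- independenceMinus2LL(wide)
    baseChisq <- indLL - satLL
    baseDf <- independenceDf(wide)
    if (df >= 1) {
      fi <- fitIndices(chisq, df, nTotal, baseChisq, baseDf)
      rmsea <- fi$rmsea; rmseaCI <- fi$ci; cfi <- fi$cfi
    } else {
      cfi <- 1  # exactly identified: fit is perfect by definition
    }
  }

  fit <- methods::new("ramFit", model = model, estimates = est, se = seVec,
                      vcov = V, minus2LL = opt$value, satMinus2LL = satLL,
                      indepMinus2LL = indLL,
                      chisq = if (is.na(chisq)) NA_real_ else chisq,
                      df = df, nTotal = as.integer(nTotal), rmsea = rmsea,
                      rmseaCI = rmseaCI, cfi = cfi, std = data.frame(),
                      converged = converged,
                      diagnostics = list(optim = opt[c("convergence", "counts",
                                                       "message")]))
  # the standardized solution is part of the reported fit, skipped in tight
  # simulation loops that only need the deviance (se = FALSE)
  if (converged && se) fit@std <- standardizedSolution(fit)
  fit
}

saturatedMinus2LLPolished <- function(wide) {
  tot <- 0
  for (X in wide) {
    if (!anyNA(X)) {
      n <- nrow(X); p <- ncol(X)
      S <- crossprod(sweep(X, 2, colMeans(X))) / n
      tot <- tot + n * (p * log(2 * pi) +
                          as.numeric(determinant(S)$modulus) + p)
    } else {
      tot <- tot + saturatedFimlOne(X, restarts = 5L, factr = 1e5)
    }
  }
  tot
}

#' RMSEA (with 95% CI) and CFI
#'
#' `RMSEA = sqrt(max(0, chisq - df) / (df (N - 1)))`; its confidence bounds
#' invert the noncentral chi-square CDF in the noncentrality `lambda`
#' (`P(X <= chisq | lambda_L) = 0.975`, `P(X <= chisq | lambda_U) = 0.025`),
#' each bound mapped through `sqrt(lambda / (df (N - 1)))` with the lower
#' bound clipped at 0.  `CFI = 1 - max(0, chisq - df) /
#' max(chisq - df, baseChisq - baseDf, 0)`, clipped to [0, 1].
#'
#' @param chisq,df model chi-square and degrees of freedom (`df >= 1`).
#' @param nTotal total sample size across groups.
#' @param baseChisq,baseDf independence-baseline chi-square and df.
#' @return list with `rmsea`, `ci` (length-2), `cfi`.
#' @export
fitIndices <- function(chisq, df, nTotal, baseChisq, baseDf) {
  stopifnot(df >= 1, baseDf >= 1, nTotal > 1)
  denom <- df * (nTotal - 1)
  rmsea <- sqrt(max(0, chisq - df) / denom)
  ncpBound <- function(target) {
    # lambda with P(chi2_df(lambda) <= chisq) = target
    if (stats::pchisq(chisq, df, ncp = 0) <= target) return(0)
    hi <- max(chisq * 2, df + 10)
    while (stats::pchisq(chisq, df, ncp = hi) > target) hi <- hi * 2
    stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - target,
                   c(0, hi), tol = 1e-10)$root
  }
  lamL <- ncpBound(0.975)
  lamU <- ncpBound(0.025)
  ci <- c(sqrt(max(0, lamL) / denom), sqrt(max(0, lamU) / denom))
  num <- max(0, chisq - df)
  den <- max(chisq - df, baseChisq - baseDf, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  list(rmsea = rmsea, ci = ci, cfi = min(1, max(0, cfi)))
}

#' Standardized solution
#'
#' Standardizes every free parameter by the model-implied total standard
#' deviations: a loading `A[i, j]` becomes `a_ij * sd(j) / sd(i)`, a
#' covariance `S[i, j]` becomes `s_ij / (sd(i) sd(j))` (for exogenous latents
#' this is the implied correlation, e.g. the change-change coupling phi), a
#' variance the proportion of total variance, a mean `m_i / sd(i)`.
#' Standardized covariances may exceed |1| for non-positive-definite latent
#' blocks; they are reported with a warning, never clipped.
#'
#' @param fit a converged [ramFit-class].
#' @return data.frame with columns `group`, `matrix`, `row`, `col`, `label`,
#'   `estimate`, `std`.
#' @export
standardizedSolution <- function(fit) {
  model <- fit@model
  imp <- impliedMoments(model, fit@estimates, full = TRUE)
  rows <- list()
  for (gname in names(model@groups)) {
    g <- model@groups[[gname]]
    C <- imp[[gname]]$cov_full
    sdv <- sqrt(pmax(diag(C), 0))
    rec <- function(mat, i, j, lbl) {
      est <- fit@estimates[lbl]
      std <- switch(mat,
        A = if (sdv[i] > 0) est * sdv[j] / sdv[i] else NA_real_,
        S = if (i == j) { if (sdv[i] > 0) est / C[i, i] else NA_real_ }
            else if (sdv[i] > 0 && sdv[j] > 0) est / (sdv[i] * sdv[j])
            else NA_real_,
        M = if (sdv[i] > 0) est / sdv[i] else NA_real_)
      data.frame(group = gname, matrix = mat, row = g$vars[i],
                 col = g$vars[j], label = lbl, estimate = unname(est),
                 std = unname(std), stringsAsFactors = FALSE)
    }
    ia <- which(!is.na(g$Albl), arr.ind = TRUE)
    for (r in seq_len(nrow(ia)))
      rows[[length(rows) + 1]] <-
        rec("A", ia[r, 1], ia[r, 2], g$Albl[ia[r, 1], ia[r, 2]])
    is_ <- which(!is.na(g$Slbl) & upper.tri(g$Slbl, diag = TRUE),
                 arr.ind = TRUE)
    for (r in seq_len(nrow(is_)))
      rows[[length(rows) + 1]] <-
        rec("S", is_[r, 1], is_[r, 2], g$Slbl[is_[r, 1], is_[r, 2]])
    im <- which(!is.na(g$Mlbl))
    for (i in im)
      rows[[length(rows) + 1]] <- rec("M", i, i, g$Mlbl[i])
  }
  out <- do.call(rbind, rows)
  offdiag <- out$matrix == "S" & out$row != out$col
  if (any(abs(out$std[offdiag]) > 1, na.rm = TRUE))
    warning("standardized covariance beyond |1| (non-positive-definite ",
            "latent block); reported unclipped")
  out
}
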