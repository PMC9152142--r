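# Data preparation and FIML likelihood evaluation.

# Manifest naming convention: a variable measured at occasion t appears in a
# model as "<variable>_T<t>" (e.g. "ACC_R.VBM_T1", "VO2peak_T3"); covariate
# manifests ("age", "sex", "education_years") are occasion-free and come from
# the participants table, with sex coded 0 = male, 1 = female.

splitManifest <- function(name) {
  m <- regmatches(name, regexec("^(.*)_T([0-9]+)$", name))[[1]]
  if (length(m) == 3) list(variable = m[2], occasion = as.integer(m[3]))
  else list(variable = name, occasion = NA_integer_)
}

# wide case-by-manifest matrices per model group; group name "all" pools
widenStudy <- function(table, model) {
  stopifnot(methods::is(table, "StudyTable"))
  meas <- table@measurements
  part <- table@participants
  lapply(model@groups, function(g) {
    ids <- if (identical(sort(unique(part$group)), character(0))) character(0)
           else part$participant_id[part$group %in%
             (if (g$name %in% c("all", "pooled")) unique(part$group) else g$name)]
    X <- matrix(NA_real_, length(ids), length(g$manifest),
                dimnames = list(ids, g$manifest))
    for (mn in g$manifest) {
      sp <- splitManifest(mn)
      if (is.na(sp$occasion)) {
        v <- part[[sp$variable]]
        if (is.null(v) && sp$variable == "sex") v <- part$sex
        if (is.null(v)) stop("covariate column not found: ", sp$variable)
        if (sp$variable == "sex") v <- as.numeric(v == "F")
        X[, mn] <- as.numeric(v)[match(ids, part$participant_id)]
      } else {
        sel <- meas$variable == sp$variable & meas$occasion == sp$occasion &
          meas$participant_id %in% ids
        X[match(meas$participant_id[sel], ids), mn] <- meas$value[sel]
      }
    }
    X[rowSums(!is.na(X)) > 0, , drop = FALSE]
  })
}

# sufficient statistics per missingness pattern (0-based indices for C++)
patternStats <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  lapply(split(seq_len(nrow(X)), key), function(rows) {
    oi <- which(obs[rows[1], ])
    Xs <- X[rows, oi, drop = FALSE]
    list(obs = as.integer(oi - 1L), n = length(rows),
         s = colSums(Xs), SS = crossprod(Xs))
  })
}

# full C++-ready structure: per-group fixed matrices, parameter position
# maps, and pattern statistics
compileModel <- function(model, wide) {
  lbl <- model@params$label
  groups <- lapply(names(model@groups), function(gname) {
    g <- model@groups[[gname]]
    nv <- length(g$vars)
    ia <- which(!is.na(g$Albl), arr.ind = TRUE)
    pA <- cbind(match(g$Albl[ia], lbl) - 1L, ia[, 1] - 1L, ia[, 2] - 1L)
    is_ <- which(!is.na(g$Slbl) & upper.tri(g$Slbl, diag = TRUE),
                 arr.ind = TRUE)
    pS <- cbind(match(g$Slbl[is_], lbl) - 1L, is_[, 1] - 1L, is_[, 2] - 1L)
    im <- which(!is.na(g$Mlbl))
    pM <- cbind(match(g$Mlbl[im], lbl) - 1L, im - 1L)
    X <- wide[[gname]]
    stopifnot(identical(colnames(X), g$manifest))
    list(A0 = g$A0, S0 = g$S0, M0 = unname(g$M0),
         pA = matrix(as.integer(pA), ncol = 3),
         pS = matrix(as.integer(pS), ncol = 3),
         pM = matrix(as.integer(pM), ncol = 2),
         man = as.integer(match(g$manifest, g$vars) - 1L),
         patterns = unname(patternStats(X)))
  })
  names(groups) <- names(model@groups)
  groups
}

#' FIML -2 log-likelihood of a RAM model
#'
#' Evaluates the full-information maximum likelihood discrepancy
#' `sum_i [k_i log(2 pi) + log|Sigma_i| + (x_i - mu_i)' Sigma_i^-1 (x_i - mu_i)]`
#' where `Sigma_i`, `mu_i` are the model-implied moments restricted to case
#' `i`'s observed variables.  Cases are grouped by missingness pattern for
#' efficiency; the result is identical to case-by-case evaluation.  A
#' non-positive-definite implied covariance yields `Inf`.
#'
#' @param model a [ramModel-class].
#' @param data a [StudyTable-class].
#' @param values named parameter values (defaults to start values).
#' @return the scalar -2 log-likelihood.
#' @export
fimlNeg2LL <- function(model, data, values = NULL) {
  if (is.null(values))
    values <- stats::setNames(model@params$start, model@params$label)
  model <- nameGroups(model)
  wide <- widenStudy(data, model)
  compiled <- compileModel(model, wide)
  theta <- unname(values[model@params$label])
  stopifnot(!anyNA(theta))
  r <- .ram_fiml(theta, unname(compiled), FALSE)
  if (!r$ok) return(Inf)
  r$value
}

# attach group names inside group structures (used for pooling rules)
nameGroups <- function(model) {
  for (gname in names(model@groups)) model@groups[[gname]]$name <- gname
  model
}

# closed-form -2lnL of the independence model (free means and variances,
# zero covariances): factorizes per variable even under missingness, with
# n-denominator MLE variance per observed subset
independenceMinus2LL <- function(wide) {
  tot <- 0
  for (X in wide) {
    for (j in seq_len(ncol(X))) {
      x <- X[, j][!is.na(X[, j])]
      n <- length(x)
      if (n == 0) next
      v <- mean((x - mean(x))^2)
      if (v <= 0) v <- .Machine$double.eps
      tot <- tot + n * (log(2 * pi) + log(v) + 1)
    }
  }
  tot
}

independenceDf <- function(wide) {
  sum(vapply(wide, function(X) {
    p <- ncol(X); p * (p + 3) / 2 - 2 * p
  }, 0))
}

# saturated model: free means + free covariances per group.  Closed form for
# complete data; FIML-optimized (same kernel) under missingness, started at
# available-case moments.
saturatedMinus2LL <- function(wide) {
  tot <- 0
  for (X in wide) {
    if (!anyNA(X)) {
      n <- nrow(X); p <- ncol(X)
      S <- crossprod(sweep(X, 2, colMeans(X))) / n
      ld <- determinant(S, logarithm = TRUE)
      if (ld$sign <= 0) stop("singular saturated covariance")
      tot <- tot + n * (p * log(2 * pi) + as.numeric(ld$modulus) + p)
    } else {
      tot <- tot + saturatedFimlOne(X)
    }
  }
  tot
}

saturatedFimlOne <- function(X, restarts = 2L, factr = 1e5) {
  p <- ncol(X)
  mu0 <- colMeans(X, na.rm = TRUE)
  S0 <- stats::cov(X, use = "pairwise.complete.obs")
  S0[is.na(S0)] <- 0
  ev <- eigen(S0, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * 1e-4)
  S0 <- ev$vectors %*% (lam * t(ev$vectors))
  vars <- colnames(X)
  g <- newRamGroup(vars, vars)
  params <- list()
  for (i in seq_len(p)) {
    g <- setMean(g, vars[i], paste0("m", i))
    params[[length(params) + 1]] <- paramRow(paste0("m", i), mu0[i])
    for (j in i:p) {
      lb <- paste0("s", i, "_", j)
      g <- setCov(g, vars[i], vars[j], lb)
      params[[length(params) + 1]] <-
        paramRow(lb, S0[i, j], lower = if (i == j) 1e-6 else -Inf)
    }
  }
  model <- ramModel(list(g1 = g), do.call(rbind, params))
  model <- nameGroups(model)
  compiled <- compileModel(model, list(g1 = X))
  opt <- optimizeCompiled(compiled, model@params, restarts = restarts,
                          factr = factr)
  opt$value
}
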