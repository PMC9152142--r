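# RAM model construction and algebra.

newRamGroup <- function(vars, manifest) {
  nv <- length(vars)
  list(vars = vars, manifest = manifest,
       A0 = matrix(0, nv, nv, dimnames = list(vars, vars)),
       Albl = matrix(NA_character_, nv, nv, dimnames = list(vars, vars)),
       S0 = matrix(0, nv, nv, dimnames = list(vars, vars)),
       Slbl = matrix(NA_character_, nv, nv, dimnames = list(vars, vars)),
       M0 = stats::setNames(numeric(nv), vars),
       Mlbl = stats::setNames(rep(NA_character_, nv), vars))
}

# set a directed path `from -> to`; `value` a number (fixed) or a label string
setPath <- function(g, from, to, value) {
  if (is.character(value)) g$Albl[to, from] <- value else g$A0[to, from] <- value
  g
}

setCov <- function(g, a, b, value) {
  if (is.character(value)) {
    g$Slbl[a, b] <- value; g$Slbl[b, a] <- value
  } else {
    g$S0[a, b] <- value; g$S0[b, a] <- value
  }
  g
}

setMean <- function(g, var, value) {
  if (is.character(value)) g$Mlbl[var] <- value else g$M0[var] <- value
  g
}

paramRow <- function(label, start, lower = -Inf, upper = Inf, sign = NA_character_) {
  data.frame(label = label, start = start, lower = lower, upper = upper,
             sign = sign, stringsAsFactors = FALSE)
}

#' Construct a RAM model
#'
#' Low-level constructor used by the model builders.  `groups` is a named
#' list of group structures (as built by the internal helpers), `params` a
#' data.frame of free-parameter labels with start values and bounds.
#'
#' @param groups named list of per-group RAM structures.
#' @param params data.frame with columns `label`, `start`, `lower`, `upper`,
#'   `sign`.
#' @return a [ramModel-class].
#' @keywords internal
ramModel <- function(groups, params) {
  params <- params[!duplicated(params$label), , drop = FALSE]
  rownames(params) <- NULL
  methods::new("ramModel", groups = groups, params = params)
}

paramLabels <- function(model) model@params$label

#' Merge or rename free-parameter labels
#'
#' Renaming a label to one that already exists merges the two parameters into
#' a single equality-constrained parameter (keeping the existing row's start
#' value and bounds); renaming to a fresh label simply relabels.  Merging is
#' how cross-group equality constraints for likelihood-ratio tests are
#' imposed: the constrained model's label set is then a subset of the free
#' model's, which `lrTest()` verifies.
#'
#' @param model a [ramModel-class].
#' @param from,to old and new label.
#' @return the modified model.
#' @export
setParamLabel <- function(model, from, to) {
  stopifnot(from %in% model@params$label)
  for (gname in names(model@groups)) {
    g <- model@groups[[gname]]
    g$Albl[g$Albl %in% from] <- to
    g$Slbl[which(g$Slbl %in% from)] <- to
    g$Mlbl[g$Mlbl %in% from] <- to
    model@groups[[gname]] <- g
  }
  if (to %in% model@params$label) {
    model@params <- model@params[model@params$label != from, , drop = FALSE]
  } else {
    model@params$label[model@params$label == from] <- to
  }
  rownames(model@params) <- NULL
  methods::validObject(model)
  model
}

#' Fix a free parameter to a constant
#'
#' Replaces every occurrence of `label` by the fixed `value`, removing the
#' parameter.  Used for boundary tests (e.g. zero change variance) and
#' nested-model construction; fixing bypasses the label's bounds by design.
#'
#' @param model a [ramModel-class].
#' @param label parameter label.
#' @param value fixed numeric value.
#' @return the modified model.
#' @export
fixParam <- function(model, label, value) {
  stopifnot(label %in% model@params$label)
  for (gname in names(model@groups)) {
    g <- model@groups[[gname]]
    hit <- which(g$Albl %in% label)
    if (length(hit)) { g$A0[hit] <- value; g$Albl[hit] <- NA_character_ }
    hit <- which(g$Slbl %in% label)
    if (length(hit)) { g$S0[hit] <- value; g$Slbl[hit] <- NA_character_ }
    hit <- which(g$Mlbl %in% label)
    if (length(hit)) { g$M0[hit] <- value; g$Mlbl[hit] <- NA_character_ }
    model@groups[[gname]] <- g
  }
  model@params <- model@params[model@params$label != label, , drop = FALSE]
  rownames(model@params) <- NULL
  methods::validObject(model)
  model
}

fillRam <- function(g, values) {
  A <- g$A0; S <- g$S0; M <- g$M0
  ia <- which(!is.na(g$Albl)); A[ia] <- values[g$Albl[ia]]
  is_ <- which(!is.na(g$Slbl)); S[is_] <- values[g$Slbl[is_]]
  im <- which(!is.na(g$Mlbl)); M[im] <- values[g$Mlbl[im]]
  list(A = A, S = S, M = M)
}

#' Model-implied moments
#'
#' Computes the RAM-implied manifest mean vector and covariance matrix for
#' each group: `Sigma = F (I-A)^-1 S (I-A)^-T F'`, `mu = F (I-A)^-1 M`, where
#' `F` filters manifest variables.
#'
#' @param model a [ramModel-class].
#' @param values named numeric vector of parameter values (defaults to start
#'   values).
#' @param full if `TRUE`, also return the covariance over all (manifest and
#'   latent) variables, used for standardization.
#' @return named list per group with elements `mu`, `sigma` (manifest), and
#'   optionally `cov_full`, `mu_full`.
#' @export
impliedMoments <- function(model, values = NULL, full = FALSE) {
  if (is.null(values))
    values <- stats::setNames(model@params$start, model@params$label)
  lapply(model@groups, function(g) {
    ram <- fillRam(g, values)
    nv <- length(g$vars)
    ImA <- diag(nv) - ram$A
    B <- tryCatch(solve(ImA), error = function(e)
      stop("singular (I - A): cyclic or ill-posed paths among {",
           paste(g$vars, collapse = ", "), "}", call. = FALSE))
    Cfull <- B %*% ram$S %*% t(B)
    Cfull <- (Cfull + t(Cfull)) / 2
    mfull <- drop(B %*% ram$M)
    names(mfull) <- g$vars
    idx <- match(g$manifest, g$vars)
    out <- list(mu = mfull[idx],
                sigma = Cfull[idx, idx, drop = FALSE])
    dimnames(out$sigma) <- list(g$manifest, g$manifest)
    if (full) {
      dimnames(Cfull) <- list(g$vars, g$vars)
      out$cov_full <- Cfull
      out$mu_full <- mfull
    }
    out
  })
}

# number of observed first+second moments over modeled manifests, per group
momentCount <- function(model) {
  sum(vapply(model@groups, function(g) {
    p <- length(g$manifest); p * (p + 3) / 2
  }, 0))
}
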