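# Shared fixtures: small study tables and models built in code.

gm <- asNamespace("gmintegrity")

# long-format StudyTable from a wide matrix of single-occasion variables
tableFromMatrix <- function(X, groups = rep("ACG", nrow(X)),
                            occasion = 1L) {
  n <- nrow(X)
  ids <- sprintf("P%03d", seq_len(n))
  meas <- do.call(rbind, lapply(colnames(X), function(v)
    data.frame(participant_id = ids, group = groups, variable = v,
               occasion = occasion, value = X[, v],
               stringsAsFactors = FALSE)))
  studyTable(meas,
             data.frame(participant_id = ids, group = groups, age = 70,
                        sex = "F", education_years = 13, icv = 1500,
                        stringsAsFactors = FALSE))
}

# StudyTable holding one variable at several occasions (columns = occasions)
tableFromOccasions <- function(M, variable = "VO2peak",
                               occasions = seq_len(ncol(M)),
                               groups = rep("ACG", nrow(M))) {
  n <- nrow(M)
  ids <- sprintf("P%03d", seq_len(n))
  meas <- do.call(rbind, lapply(seq_along(occasions), function(j)
    data.frame(participant_id = ids, group = groups, variable = variable,
               occasion = as.integer(occasions[j]), value = M[, j],
               stringsAsFactors = FALSE)))
  meas <- meas[!is.na(meas$value), , drop = FALSE]
  studyTable(meas,
             data.frame(participant_id = ids, group = groups, age = 70,
                        sex = "F", education_years = 13, icv = 1500,
                        stringsAsFactors = FALSE))
}

# a random small one-factor model + complete or holey data, for FIML
# property checks; returns list(model, table, values)
randomFactorModel <- function(n = 40, p = 3, missing = FALSE, seed = 1) {
  set.seed(seed)
  lam <- c(1, runif(p - 1, 0.4, 1.5) * sample(c(-1, 1), p - 1, TRUE))
  eta <- rnorm(n)
  X <- sapply(seq_len(p), function(j)
    runif(1, -1, 1) + lam[j] * eta + rnorm(n, 0, runif(1, 0.4, 1)))
  colnames(X) <- paste0("y", seq_len(p))
  if (missing)
    for (j in seq_len(p)) X[sample(n, ceiling(n * 0.15)), j] <- NA
  vars <- c(paste0("y", seq_len(p), "_T1"), "f")
  g <- gm$newRamGroup(vars, vars[seq_len(p)])
  params <- list()
  for (j in seq_len(p)) {
    yj <- vars[j]
    lb <- paste0("l", j)
    if (j == 1) g <- gm$setPath(g, "f", yj, 1)
    else {
      g <- gm$setPath(g, "f", yj, lb)
      params[[length(params) + 1]] <- gm$paramRow(lb, 0.5)
    }
    g <- gm$setCov(g, yj, yj, paste0("th", j))
    g <- gm$setMean(g, yj, paste0("m", j))
    params[[length(params) + 1]] <- gm$paramRow(paste0("th", j), 0.5,
                                                lower = 1e-6)
    params[[length(params) + 1]] <- gm$paramRow(paste0("m", j), 0)
  }
  g <- gm$setCov(g, "f", "f", "psi")
  params[[length(params) + 1]] <- gm$paramRow("psi", 0.5, lower = 1e-6)
  model <- gm$ramModel(list(all = g), do.call(rbind, params))
  tab <- tableFromMatrix(`colnames<-`(X, paste0("y", seq_len(p))))
  list(model = model, table = tab, X = X)
}

# convenience: standardize every variable of a table
standardizeAll <- function(table) {
  for (v in unique(measurements(table)$variable))
    table <- stackStandardize(table, v)
  table
}
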