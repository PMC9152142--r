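# Analytic sensitivity computations: the minimal detectable
# repeated-measures interaction effect (Cohen's f, noncentral-F power
# inversion) and the minimal detectable correlation (exact sample-correlation
# distribution or Fisher-z approximation).

#' Power/sensitivity configuration
#'
#' @param alpha type-I error rate.
#' @param power target power (must exceed `alpha`).
#' @param nTotal total sample size across groups.
#' @param groups number of groups.
#' @param measurements number of repeated measurements.
#' @param rho assumed correlation among repeated measures (conventional
#'   default 0.5).
#' @param epsilon nonsphericity correction in (0, 1] (default 1).
#' @param tails `"one"` or `"two"` for the correlation test.
#' @return validated list of class `powerConfig`.
#' @export
powerConfig <- function(alpha = 0.05, power = 0.95, nTotal = 75L,
                        groups = 2L, measurements = 3L, rho = 0.5,
                        epsilon = 1, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(alpha > 0, alpha < 1, power > alpha, power < 1,
            nTotal > groups, groups >= 2, measurements >= 2,
            rho > -1, rho < 1, epsilon > 0, epsilon <= 1)
  structure(list(alpha = alpha, power = power, nTotal = nTotal,
                 groups = groups, measurements = measurements, rho = rho,
                 epsilon = epsilon, tails = tails),
            class = "powerConfig")
}

# power of the within-between interaction F test at effect size f
interactionPower <- function(f, cfg) {
  df1 <- (cfg$groups - 1) * (cfg$measurements - 1) * cfg$epsilon
  df2 <- (cfg$nTotal - cfg$groups) * (cfg$measurements - 1) * cfg$epsilon
  lambda <- f^2 * cfg$nTotal * cfg$measurements * cfg$epsilon / (1 - cfg$rho)
  crit <- stats::qf(1 - cfg$alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

bisect <- function(fun, lower, upper, tol = 1e-6) {
  fl <- fun(lower); fu <- fun(upper)
  if (is.na(fl) || is.na(fu) || fl * fu > 0)
    stop("no root bracketed in (", lower, ", ", upper, ")")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- fun(mid)
    if (fl * fm <= 0) { upper <- mid; fu <- fm } else { lower <- mid; fl <- fm }
  }
  (lower + upper) / 2
}

#' Minimal detectable repeated-measures interaction effect (Cohen's f)
#'
#' Inverts noncentral-F power for the within-between (time-by-group)
#' interaction: numerator df `(g-1)(m-1) eps`, denominator df
#' `(N-g)(m-1) eps`, noncentrality `lambda = f^2 N m eps / (1 - rho)`;
#' power is the upper tail of the noncentral F beyond the central-F critical
#' value at `alpha`.  The root in f is found by bisection to 1e-6.
#'
#' @param config a [powerConfig()].
#' @return the minimal detectable Cohen's f.
#' @export
sensitivityF <- function(config = powerConfig()) {
  stopifnot(inherits(config, "powerConfig"))
  bisect(function(f) interactionPower(f, config) - config$power, 1e-8, 10)
}

# exact density of the sample correlation r given population rho (bivariate
# normal, Hotelling's form with a Gaussian hypergeometric factor)
corrDensity <- function(r, rho, n) {
  hyp2f1 <- function(z, a = 0.5, b = 0.5, cc = n - 0.5) {
    term <- 1; total <- 1
    for (k in 0:500) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
      total <- total + term
      if (abs(term) < 1e-16 * abs(total)) break
    }
    total
  }
  ld <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log(1 - rho^2) +
    ((n - 4) / 2) * log(1 - r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log(1 - rho * r)
  exp(ld) * vapply(seq_along(r), function(i) hyp2f1((1 + rho * r[i]) / 2), 0)
}

# power of the correlation test (H0: rho = 0) at population rho
corrPower <- function(rho, cfg, method) {
  n <- cfg$nTotal
  a <- if (cfg$tails == "one") cfg$alpha else cfg$alpha / 2
  if (method == "fisher") {
    za <- stats::qnorm(1 - a)
    stats::pnorm(sqrt(n - 3) * (atanh(rho)) - za)
  } else {
    tc <- stats::qt(1 - a, n - 2)
    rc <- tc / sqrt(n - 2 + tc^2)  # null critical r
    up <- stats::integrate(corrDensity, rc, 1, rho = rho, n = n,
                           rel.tol = 1e-10)$value
    if (cfg$tails == "two")
      up <- up + stats::integrate(corrDensity, -1, -rc, rho = rho, n = n,
                                  rel.tol = 1e-10)$value
    up
  }
}

#' Minimal detectable correlation
#'
#' Solves power(`rho`) = target for the test of a zero correlation.  In
#' `"exact"` mode the power is integrated from the exact distribution of the
#' sample correlation under a bivariate normal with correlation `rho`
#' (critical value from the null t transform); `"fisher"` uses the Fisher-z
#' normal approximation `tanh((z_{1-alpha} + z_{power}) / sqrt(N - 3))`.
#' The root is found by bisection to 1e-6.
#'
#' @param config a [powerConfig()] (uses `alpha`, `power`, `nTotal`,
#'   `tails`).
#' @param method `"exact"` or `"fisher"`.
#' @return the minimal detectable Pearson r.
#' @export
sensitivityR <- function(config = powerConfig(), method = c("exact",
                                                            "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "powerConfig"), config$nTotal >= 4)
  # adaptive upper bracket: the exact density is numerically delicate at
  # extreme rho, so stop at the first grid point whose power exceeds target
  upper <- NA_real_
  for (u in c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 0.9, 0.95, 0.99)) {
    if (corrPower(u, config, method) >= config$power) { upper <- u; break }
  }
  if (is.na(upper)) stop("no detectable correlation below 0.99 at this N")
  bisect(function(rho) corrPower(rho, config, method) - config$power,
         1e-8, upper)
}
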