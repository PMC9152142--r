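# Preprocessing operators: ICV adjustment, longitudinal standardization,
# univariate and Mahalanobis outlier screens, compliance classification.
#
# Fixed pipeline order (asserted by runPipeline): univariate screen on raw
# values -> multivariate screen -> ICV adjustment (VBM only) -> compliance
# exclusion -> stack-standardization.  Sample SD (n-1) throughout.

#' Adjust ROI volumes for intracranial volume
#'
#' Analysis-of-covariance adjustment: `adjusted = raw - b * (ICV - mean
#' ICV)`, where `b` is the least-squares slope of the ROI volume on ICV over
#' non-missing pairs.  Adjusted values have zero sample covariance with ICV;
#' missing inputs stay missing.
#'
#' @param values per-participant ROI volumes (may contain `NA`).
#' @param icv per-participant intracranial volumes, same length.
#' @return adjusted volumes, same length and missingness as `values`.
#' @export
adjustICV <- function(values, icv) {
  stopifnot(length(values) == length(icv))
  ok <- !is.na(values) & !is.na(icv)
  if (sum(ok) < 3) stop("need at least 3 non-missing (volume, ICV) pairs")
  if (stats::var(icv[ok]) <= 0) stop("ICV variance must be positive")
  b <- unname(stats::coef(stats::lm(values[ok] ~ icv[ok]))[2])
  out <- values
  out[ok] <- values[ok] - b * (icv[ok] - mean(icv[ok]))
  out
}

#' Longitudinal (stacked) standardization
#'
#' Rescales one variable to pooled mean 0 and pooled sample SD 1 across all
#' occasions jointly (values from all time points stacked first), preserving
#' relative mean differences between occasions: a single shared affine
#' transform, never per-occasion scaling.  Missing cells stay absent.
#'
#' @param table a [StudyTable-class].
#' @param variable variable token to rescale (e.g. `"ACC_R.VBM"`).
#' @return the table with the variable rescaled.
#' @export
stackStandardize <- function(table, variable) {
  m <- table@measurements
  sel <- m$variable == variable
  x <- m$value[sel]
  if (length(x) < 2) stop("need >= 2 non-missing values for ", variable)
  s <- stats::sd(x)
  if (s <= 0) stop("pooled SD is zero for variable ", variable)
  m$value[sel] <- (x - mean(x)) / s
  methods::initialize(table, measurements = m)
}

#' Univariate outlier screen
#'
#' Flags cells further than `thresholdSD` sample SDs from the mean, with
#' mean and SD computed per (variable, occasion) group over non-missing
#' values; flagged cells are removed from the returned table.  Zero-spread
#' groups flag nothing.
#'
#' @param table a [StudyTable-class].
#' @param thresholdSD flagging threshold in SD units (default 4).
#' @return list with `table` (screened) and `report` (data.frame of flagged
#'   cells with z-scores, plus counts as attributes `cells_examined`,
#'   `cells_discarded`).
#' @export
flagUnivariateOutliers <- function(table, thresholdSD = 4) {
  m <- table@measurements
  z <- rep(NA_real_, nrow(m))
  for (key in unique(paste(m$variable, m$occasion))) {
    idx <- which(paste(m$variable, m$occasion) == key)
    if (length(idx) < 3) next
    mu <- mean(m$value[idx]); s <- stats::sd(m$value[idx])
    if (s > 0) z[idx] <- (m$value[idx] - mu) / s
  }
  flag <- !is.na(z) & abs(z) > thresholdSD
  report <- data.frame(participant_id = m$participant_id[flag],
                       variable = m$variable[flag],
                       occasion = m$occasion[flag],
                       z = z[flag], stringsAsFactors = FALSE)
  attr(report, "cells_examined") <- nrow(m)
  attr(report, "cells_discarded") <- sum(flag)
  list(table = methods::initialize(table,
                                   measurements = m[!flag, , drop = FALSE]),
       report = report)
}

#' Multivariate (Mahalanobis) outlier screen
#'
#' For one variable, takes the complete cases across all its occasions,
#' computes each case's squared Mahalanobis distance from the complete-case
#' mean under the classical product-moment covariance, and flags cases whose
#' distance exceeds the chi-square quantile at probability `1 - criterion`
#' with df = number of occasions.  All occasions of a flagged case are
#' removed (abnormal longitudinal patterns, not single spikes).
#'
#' @param table a [StudyTable-class].
#' @param variable variable token.
#' @param criterion tail probability for the chi-square cutoff (0.001).
#' @return list with `table` and `report` (flagged cases with `distance2`
#'   and `threshold`), counts as attributes as in
#'   [flagUnivariateOutliers()].
#' @export
flagMultivariateOutliers <- function(table, variable, criterion = 0.001) {
  m <- table@measurements
  sel <- m$variable == variable
  occ <- sort(unique(m$occasion[sel]))
  df <- length(occ)
  wide <- stats::reshape(m[sel, c("participant_id", "occasion", "value")],
                         idvar = "participant_id", timevar = "occasion",
                         direction = "wide")
  X <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(X)
  Xc <- X[complete, , drop = FALSE]
  if (nrow(Xc) < df + 2)
    stop("need at least df + 2 complete cases for ", variable)
  S <- stats::cov(Xc)
  if (abs(det(S)) < 1e-300)
    stop("singular covariance for ", variable)
  d2 <- stats::mahalanobis(Xc, colMeans(Xc), S)
  threshold <- stats::qchisq(1 - criterion, df = df)
  bad <- wide$participant_id[complete][d2 > threshold]
  report <- data.frame(participant_id = wide$participant_id[complete],
                       distance2 = d2, threshold = threshold,
                       flagged = d2 > threshold, stringsAsFactors = FALSE)
  report <- report[report$flagged, , drop = FALSE]
  attr(report, "cells_examined") <- nrow(Xc)
  attr(report, "cells_discarded") <- length(bad)
  drop <- sel & m$participant_id %in% bad
  list(table = methods::initialize(table,
                                   measurements = m[!drop, , drop = FALSE]),
       report = report)
}

#' Classify training compliance
#'
#' A participant is non-compliant if total activity falls below
#' `weeksRequired * weeklyMinutes` minutes (default 21 weeks x 90 min =
#' 1890), if any zero-activity pause exceeds `maxPauseWeeks` consecutive
#' weeks, or (when watts are required to be non-decreasing, i.e. exercisers)
#' if the ordinary least-squares slope of weekly watts over active weeks is
#' negative.  Weeks absent from the log count as zero-activity weeks.
#'
#' @param log data.frame with `week`, `minutes`, `watts` for one
#'   participant (may have zero rows).
#' @param weeksRequired,weeklyMinutes,maxPauseWeeks compliance thresholds.
#' @param requireNondecreasingWatts apply the wattage-trend criterion.
#' @return list (`complianceRecord`): `total_minutes`,
#'   `longest_pause_weeks`, `wattage_trend` (W/week), `compliant`,
#'   `reasons` (subset of `minutes`, `pause`, `watts`; empty iff compliant).
#' @export
classifyCompliance <- function(log, weeksRequired = 21L, weeklyMinutes = 90,
                               maxPauseWeeks = 2L,
                               requireNondecreasingWatts = FALSE) {
  if (nrow(log) && is.unsorted(log$week, strictly = TRUE))
    stop("weeks must be strictly increasing")
  horizon <- max(26L, if (nrow(log)) max(log$week) else 0L)
  minutes <- numeric(horizon)
  watts <- rep(NA_real_, horizon)
  if (nrow(log)) {
    minutes[log$week] <- log$minutes
    watts[log$week] <- log$watts
  }
  total <- sum(minutes)
  runs <- rle(minutes == 0)
  pause <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  active <- which(minutes > 0 & !is.na(watts))
  trend <- if (length(active) >= 2)
    unname(stats::coef(stats::lm(watts[active] ~ active))[2]) else NA_real_
  reasons <- character(0)
  if (total < weeksRequired * weeklyMinutes) reasons <- c(reasons, "minutes")
  # an empty log is a minutes violation, not additionally a pause
  if (nrow(log) && pause > maxPauseWeeks) reasons <- c(reasons, "pause")
  if (requireNondecreasingWatts && !is.na(trend) && trend < 0)
    reasons <- c(reasons, "watts")
  structure(list(total_minutes = total,
                 longest_pause_weeks = as.integer(pause),
                 wattage_trend = trend,
                 compliant = length(reasons) == 0L,
                 reasons = reasons),
            class = "complianceRecord")
}

#' @export
print.complianceRecord <- function(x, ...) {
  cat(sprintf("compliance: %s (total %.0f min, longest pause %d wk%s)\n",
              if (x$compliant) "compliant" else
                paste("non-compliant:", paste(x$reasons, collapse = ", ")),
              x$total_minutes, x$longest_pause_weeks,
              if (is.na(x$wattage_trend)) "" else
                sprintf(", watt trend %.2f W/wk", x$wattage_trend)))
  invisible(x)
}
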