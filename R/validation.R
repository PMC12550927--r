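# Assay-validation statistics: precision (CV), analytical limits
# (LoB/LoD/LoQ), linearity, nonparametric reference intervals,
# Levey-Jennings QC flags, storage-stability recovery, and copy-number
# distribution tables.

#' Replicate precision (coefficient of variation)
#'
#' Sample SD (n-1 denominator) and CV = 100 * sd / mean. At a true level of
#' zero the CV is undefined; the result then carries `cvPercent = NA` and the
#' absolute SD stands in (`cvUndefined = TRUE`), the convention used for
#' 0-copy precision levels.
#'
#' @param values replicate measurements (n >= 2).
#' @param label level label.
#' @param scope `"within_run"` or `"between_run"`.
#' @return data.frame with `label`, `scope`, `n`, `mean`, `sd`, `cvPercent`,
#'   `cvUndefined`.
#' @examples
#' computeCV(c(8, 10, 12))$cvPercent # 20
#' @export
computeCV <- function(values, label = "", scope = c("within_run", "between_run")) {
  scope <- match.arg(scope)
  if (length(values) < 2) {
    ddStop("precision needs at least 2 replicates", "ddInsufficientDataError")
  }
  m <- mean(values)
  s <- stats::sd(values)
  undef <- m == 0
  data.frame(
    label = label, scope = scope, n = length(values),
    mean = m, sd = s,
    cvPercent = if (undef) NA_real_ else 100 * s / m,
    cvUndefined = undef,
    stringsAsFactors = FALSE
  )
}

#' Limit of blank
#'
#' Nonparametric 95th percentile of replicate blank measurements
#' (rank (n+1)p with linear interpolation). All-zero blanks give LoB = 0.
#'
#' @param blankValues blank measurements.
#' @param nRequired minimum number of blanks (default 20).
#' @return LoB in the measurement units.
#' @examples
#' limitOfBlank(rep(0, 20)) # 0
#' @export
limitOfBlank <- function(blankValues, nRequired = 20) {
  if (length(blankValues) < nRequired) {
    ddStop(sprintf("limit of blank needs >= %d blanks", nRequired),
           "ddInsufficientDataError")
  }
  percentileNplus1(blankValues, 0.95)
}

#' Limit of detection
#'
#' `LoD = LoB + 1.6 * SD`, with the SD taken from replicates of a low-level
#' sample. (The 1.6 multiplier is used verbatim; the common CLSI value is
#' 1.645.)
#'
#' @param lob limit of blank.
#' @param sdLowLevel SD of the low-level replicates (>= 0).
#' @return LoD.
#' @examples
#' limitOfDetection(0, 1.875) # 3
#' @export
limitOfDetection <- function(lob, sdLowLevel) {
  if (sdLowLevel < 0) ddStop("SD must be >= 0", "ddConfigError")
  lob + 1.6 * sdLowLevel
}

#' Limit of quantification
#'
#' The lowest tested concentration whose replicate CV is below the threshold
#' (default 25%, the usual dPCR criterion). If no level qualifies the LoQ is
#' `NA` with `determined = FALSE`.
#'
#' @param levels list of `list(conc = , values = )` entries (each >= 2
#'   replicates).
#' @param cvThreshold CV threshold, percent.
#' @return list with `loq`, `determined`, and the per-level CV table.
#' @examples
#' limitOfQuantification(list(
#'   list(conc = 10, values = c(5, 10, 15)),
#'   list(conc = 20, values = c(19, 20, 21))
#' ))$loq # 20
#' @export
limitOfQuantification <- function(levels, cvThreshold = 25) {
  if (length(levels) < 1) {
    ddStop("need at least one concentration level", "ddInsufficientDataError")
  }
  tab <- do.call(rbind, lapply(levels, function(l) {
    cv <- computeCV(l$values, label = as.character(l$conc))
    data.frame(conc = l$conc, n = cv$n, cvPercent = cv$cvPercent)
  }))
  ok <- !is.na(tab$cvPercent) & tab$cvPercent < cvThreshold
  list(
    loq = if (any(ok)) min(tab$conc[ok]) else NA_real_,
    determined = any(ok),
    levels = tab
  )
}

#' Linearity of a dilution series
#'
#' Ordinary least squares of measured on expected concentration with the
#' standard coefficient of determination.
#'
#' @param expected,measured numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `rSquared`.
#' @examples
#' linearityFit(c(0, 1, 2), c(0, 2, 4)) # slope 2, r^2 1
#' @export
linearityFit <- function(expected, measured) {
  if (length(expected) < 3 || length(expected) != length(measured)) {
    ddStop("need >= 3 paired points", "ddInsufficientDataError")
  }
  if (stats::sd(expected) == 0) {
    ddStop("expected concentrations are constant: fit is degenerate",
           "ddConfigError")
  }
  fit <- stats::lm(measured ~ expected)
  tss <- sum((measured - mean(measured))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    rSquared = if (tss == 0) 1 else 1 - rss / tss
  )
}

#' Nonparametric reference interval bound
#'
#' Lower percentile (default 2.5th) of a screening population, restricted to
#' samples at or above the minimum gestational age, using rank (n+1)p with
#' linear interpolation. Fewer than 120 eligible samples makes the
#' nonparametric percentile unreliable and sets `reliable = FALSE`.
#'
#' @param values measurements (copies/µL blood).
#' @param p lower-tail probability (default 0.025).
#' @param gestationalWeeks optional per-sample gestational ages; samples
#'   below `minWeeks` are excluded.
#' @param minWeeks minimum gestational age, weeks.
#' @return list with `n`, `p`, `cutoff`, `reliable`, `method`.
#' @examples
#' referenceInterval(1:1000)$cutoff # 25.025
#' @export
referenceInterval <- function(values, p = 0.025, gestationalWeeks = NULL,
                              minWeeks = 34) {
  if (!is.null(gestationalWeeks)) {
    if (length(gestationalWeeks) != length(values)) {
      ddStop("gestationalWeeks must match values in length", "ddSchemaError")
    }
    values <- values[gestationalWeeks >= minWeeks]
  }
  n <- length(values)
  if (n == 0) ddStop("no eligible samples", "ddInsufficientDataError")
  list(
    n = n, p = p,
    cutoff = percentileNplus1(values, p),
    reliable = n >= 120,
    method = "nonparametric (n+1)p rank, linear interpolation"
  )
}

#' Levey-Jennings control flags
#'
#' Flags each control value out of control when it deviates more than 2 SD
#' from the target mean (the 1-2s acceptance rule); two consecutive values
#' beyond 2 SD on the same side are additionally reported as a 2-2s advisory.
#'
#' @param qcValues control measurements in run order.
#' @param mean,sd target mean and SD (sd > 0).
#' @return data.frame with `value`, `deviationSd`, `outOfControl`,
#'   `advisory22s`.
#' @examples
#' leveyJenningsFlags(c(10, 10.5, 15), mean = 10, sd = 1)$outOfControl
#' @export
leveyJenningsFlags <- function(qcValues, mean, sd) {
  if (sd <= 0) ddStop("sd must be > 0", "ddConfigError")
  z <- (qcValues - mean) / sd
  out <- abs(z) > 2
  adv <- logical(length(z))
  if (length(z) >= 2) {
    same <- out[-1] & out[-length(z)] & (sign(z[-1]) == sign(z[-length(z)]))
    adv[-1] <- same
  }
  data.frame(
    value = qcValues, deviationSd = z,
    outOfControl = out, advisory22s = adv
  )
}

#' Storage-stability recovery
#'
#' Recovery = 100 * mean(day N) / mean(day 0); acceptable within ±10%
#' (90–110%).
#'
#' @param day0Values,dayNValues replicate measurements on day 0 and day N.
#' @return list with `recoveryPercent` and `pass`.
#' @examples
#' stabilityRecovery(c(99, 101), c(94, 96)) # 95%, pass
#' @export
stabilityRecovery <- function(day0Values, dayNValues) {
  if (length(day0Values) < 1 || length(dayNValues) < 1) {
    ddStop("need measurements on both days", "ddInsufficientDataError")
  }
  m0 <- mean(day0Values)
  if (m0 == 0) {
    ddStop("day-0 mean is zero: recovery undefined", "ddConfigError")
  }
  rec <- 100 * mean(dayNValues) / m0
  list(recoveryPercent = rec, pass = rec >= 90 && rec <= 110)
}

#' Copy-number distribution table
#'
#' Counts and percentages (rounded half-up to one decimal) of integer
#' copy-number calls in a cohort.
#'
#' @param cn integer copy-number calls, or a pre-tabulated named count vector
#'   (names = copy numbers).
#' @param n total cohort size; defaults to `length(cn)` (or `sum(cn)` for
#'   counts).
#' @return data.frame with `copyNumber`, `count`, `percent`.
#' @examples
#' cnDistributionTable(c(2, 2, 2, 3)) # 75% / 25%
#' @export
cnDistributionTable <- function(cn, n = NULL) {
  if (!is.null(names(cn))) {
    counts <- structure(as.integer(cn), names = names(cn))
  } else {
    if (length(cn) < 1) ddStop("empty cohort", "ddInsufficientDataError")
    tab <- table(cn)
    counts <- structure(as.integer(tab), names = names(tab))
  }
  if (is.null(n)) n <- sum(counts)
  data.frame(
    copyNumber = as.integer(names(counts)),
    count = unname(counts),
    percent = roundHalfUp(100 * unname(counts) / n, 1)
  )
}
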