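#' Round half away from zero
#'
#' Decimal rounding with ties going up (1.25 -> 1.3 at one decimal), the
#' convention used for reported copy numbers and table percentages. Base
#' [round()] uses banker's rounding, which would print 0.5 -> 0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.94, 1) # 0.9
#' roundHalfUp(1.25, 1) # 1.3
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  # small epsilon guards against binary representation of e.g. 2.5 stored
  # as 2.4999999999999996
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# canonical target order; channel assignment lives in AssayConfig@channelMap
ddTargets <- function() c("SMN1", "RPP30", "SMN2", "TREC")

# nonparametric percentile with rank (n+1)p and linear interpolation
# (quantile type 6), the convention documented for LoB and reference
# intervals
percentileNplus1 <- function(x, p) {
  # + 0 normalises IEEE negative zero from the interpolation arithmetic
  unname(stats::quantile(x, probs = p, type = 6, names = FALSE)) + 0
}
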