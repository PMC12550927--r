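# Poisson absolute quantification and unit conversion.
#
# With N droplets of volume v and nNeg negatives, the mean copies per
# droplet is lambda = -ln(nNeg/N) and the reaction concentration
# lambda / v. Copy number is referenced to RPP30 at two copies per genome,
# and blood units follow
#   copies/uL blood = (copies per 20 uL well / 8 uL input DNA)
#                     x (elution volume / 3 uL blood per punch).

#' Poisson concentration from droplet counts
#'
#' @param nPositive positive droplet count.
#' @param nTotal total accepted droplets (> 0).
#' @param dropletVolume droplet volume in nL.
#' @param conf confidence level for the interval.
#' @return list with `lambda` (copies/droplet), `concReaction` (copies/µL of
#'   reaction) and `ci` (confidence interval on `concReaction`, normal
#'   approximation on the log scale).
#' @examples
#' poissonConcentration(10000, 20000, 0.85)$concReaction # ~815.5
#' @export
poissonConcentration <- function(nPositive, nTotal, dropletVolume = 0.85,
                                 conf = 0.95) {
  if (nTotal <= 0 || nPositive < 0 || nPositive > nTotal) {
    ddStop("need 0 <= nPositive <= nTotal and nTotal > 0", "ddConfigError")
  }
  if (nPositive == nTotal) {
    ddStop(
      "all droplets positive: concentration is unresolvable (saturation)",
      "ddSaturationError"
    )
  }
  pNeg <- (nTotal - nPositive) / nTotal
  lambda <- -log(pNeg)
  vUl <- dropletVolume * 1e-3 # nL -> uL
  conc <- lambda / vUl
  # var(lambda-hat) ~ (1 - pNeg) / (n * pNeg)
  seLambda <- sqrt((1 - pNeg) / (nTotal * pNeg))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, lambda - z * seLambda), lambda + z * seLambda) / vUl
  list(lambda = lambda, concReaction = conc, ci = ci)
}

#' RPP30-referenced copy number
#'
#' Copy number is `2 * concTarget / concRpp30`, with RPP30 fixed at two
#' copies per genome. The reported value is rounded half-up to one decimal
#' (the convention of printed copy-number tables); the integer call is the
#' nearest integer with ties (x.5) rounded up.
#'
#' @param concTarget,concRpp30 concentrations in the same units.
#' @return list with `cn`, `cnReported`, `cnInteger`.
#' @examples
#' copyNumber(0.47 * 100, 100) # cn 0.94 -> reported 0.9, integer 1
#' @export
copyNumber <- function(concTarget, concRpp30) {
  if (concRpp30 <= 0) {
    ddStop("RPP30 concentration is zero: no reference for copy number",
           "ddNoReferenceError")
  }
  cn <- 2 * concTarget / concRpp30
  list(
    cn = cn,
    cnReported = roundHalfUp(cn, 1),
    cnInteger = as.integer(roundHalfUp(cn, 0))
  )
}

#' Convert copies per well to copies/µL blood
#'
#' `concBlood = (copiesPerWell / inputDnaVolume) * (elutionVolume /
#' bloodPerPunch)`. With the defaults (8 µL input, 50 µL elution, 3 µL blood
#' per punch) the factor is 25/12 per µL input, i.e. 2000 copies/well (100
#' copies/µL reaction) -> 4167 copies/µL blood and 100,000 copies/well ->
#' ~208,300 copies/µL blood, the recommended loading window.
#'
#' @param copiesPerWell template copies in one well.
#' @param cfg an [AssayConfig-class] supplying the volumes.
#' @return copies/µL blood.
#' @examples
#' toBloodConcentration(2000) # ~4167
#' @export
toBloodConcentration <- function(copiesPerWell, cfg = AssayConfig()) {
  (copiesPerWell / cfg@inputDnaVolume) * (cfg@elutionVolume / cfg@bloodPerPunch)
}

#' Quantify a called well
#'
#' Computes, per target: the Poisson rate, reaction concentration, copies per
#' well (`concReaction * wellVolume`) and blood concentration; SMN1 and SMN2
#' additionally receive RPP30-referenced copy numbers (RPP30 itself is the
#' reference, copy number exactly 2; TREC has none). A zero RPP30
#' concentration leaves the SMN copy numbers `NA` and flags the well
#' `"no_reference"` — such samples fail qualification downstream.
#'
#' @param calls data.frame from [callWell()].
#' @param cfg an [AssayConfig-class].
#' @return a [WellQuant-class].
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 5000L)
#' w <- simulateWell(SampleTruth(trecBlood = 300), cfg, seed = 4)
#' quantifyWell(callWell(w, cfg, overrideQC = TRUE), cfg)
#' @export
quantifyWell <- function(calls, cfg = AssayConfig()) {
  if (!all(ddTargets() %in% calls$target)) {
    ddStop("calls must contain all four targets", "ddSchemaError")
  }
  calls <- calls[match(ddTargets(), calls$target), ]
  pc <- lapply(seq_len(nrow(calls)), function(i) {
    poissonConcentration(calls$nPositive[i],
                         calls$nPositive[i] + calls$nNegative[i],
                         cfg@dropletVolume)
  })
  lambda <- vapply(pc, `[[`, numeric(1), "lambda")
  concReaction <- vapply(pc, `[[`, numeric(1), "concReaction")
  ciLow <- vapply(pc, function(p) p$ci[1], numeric(1))
  ciHigh <- vapply(pc, function(p) p$ci[2], numeric(1))
  copiesPerWell <- concReaction * cfg@wellVolume
  concBlood <- toBloodConcentration(copiesPerWell, cfg)
  rpp30Conc <- concReaction[match("RPP30", calls$target)]
  flags <- character()
  cn <- cnReported <- rep(NA_real_, nrow(calls))
  cnInteger <- rep(NA_integer_, nrow(calls))
  for (tg in c("SMN1", "SMN2")) {
    i <- match(tg, calls$target)
    if (rpp30Conc > 0) {
      cc <- copyNumber(concReaction[i], rpp30Conc)
      cn[i] <- cc$cn
      cnReported[i] <- cc$cnReported
      cnInteger[i] <- cc$cnInteger
    } else {
      flags <- unique(c(flags, "no_reference"))
    }
  }
  i <- match("RPP30", calls$target)
  cn[i] <- 2
  cnReported[i] <- 2
  cnInteger[i] <- 2L
  new("WellQuant",
    wellId = calls$wellId[1], sampleId = calls$sampleId[1],
    quant = data.frame(
      target = calls$target,
      nPositive = calls$nPositive, nNegative = calls$nNegative,
      lambda = lambda, concReaction = concReaction,
      copiesPerWell = copiesPerWell, concBlood = concBlood,
      cn = cn, cnReported = cnReported, cnInteger = cnInteger,
      ciLow = ciLow, ciHigh = ciHigh,
      stringsAsFactors = FALSE
    ),
    flags = flags
  )
}

# convenience extractors used by screening and validation
targetRow <- function(wq, target) {
  q <- quantTable(wq)
  q[match(target, q$target), ]
}

#' @rdname ddScreen-accessors
#' @param target one of `"SMN1"`, `"RPP30"`, `"SMN2"`, `"TREC"`.
#' @export
bloodConcentration <- function(x, target) {
  targetRow(x, target)$concBlood
}
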