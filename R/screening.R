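# The screening decision engine: sample qualification by RPP30 loading,
# TREC classification for SCID, SMN1/SMN2 classification for SMA, and the
# second-tier Sanger decision table that excludes allele dropout.

#' Sample qualification by RPP30 loading
#'
#' A specimen is qualified when its RPP30 blood concentration strictly
#' exceeds the cutoff (default 4200 copies/µL blood), ensuring enough DNA
#' was loaded for copy-number determination and TREC quantification.
#'
#' @param rpp30Blood RPP30 concentration, copies/µL blood.
#' @param cutoffs a [ScreenCutoffs-class].
#' @return logical.
#' @examples
#' qualifySample(10932) # TRUE
#' qualifySample(4)     # FALSE
#' qualifySample(4200)  # FALSE (strict >)
#' @export
qualifySample <- function(rpp30Blood, cutoffs = ScreenCutoffs()) {
  rpp30Blood > cutoffs@rpp30MinBlood
}

#' TREC classification for SCID screening
#'
#' Unqualified when the sample fails RPP30 qualification; otherwise Negative
#' (normal) when TREC strictly exceeds the cutoff (default 57 copies/µL
#' blood), else Positive — a screen positive triggering the
#' re-punch/retest/recall workflow.
#'
#' @param trecBlood TREC concentration, copies/µL blood.
#' @inheritParams qualifySample
#' @return `"Negative"`, `"Positive"` or `"Unqualified"`.
#' @examples
#' classifyTrec(326, 10932) # Negative
#' classifyTrec(0, 144892)  # Positive
#' classifyTrec(0, 0)       # Unqualified
#' @export
classifyTrec <- function(trecBlood, rpp30Blood, cutoffs = ScreenCutoffs()) {
  if (!qualifySample(rpp30Blood, cutoffs)) {
    "Unqualified"
  } else if (trecBlood > cutoffs@trecCutoffBlood) {
    "Negative"
  } else {
    "Positive"
  }
}

#' SMA classification from integer copy numbers
#'
#' SMN1 = 0 is presumptive SMA (second-tier confirmation required to exclude
#' allele dropout); SMN1 = 1 is a carrier (with an advisory that compound
#' heterozygotes need sequencing follow-up); SMN1 >= 2 is normal.
#' Unqualified samples are not classified.
#'
#' @param smn1Cn,smn2Cn integer copy numbers (>= 0).
#' @param qualified logical from [qualifySample()].
#' @return list with `smaClass` and `needsSecondTier`.
#' @examples
#' classifySmn(2, 1)$smaClass # "Normal"
#' classifySmn(0, 2)          # presumptive SMA, second tier required
#' @export
classifySmn <- function(smn1Cn, smn2Cn, qualified = TRUE) {
  if (smn1Cn < 0 || smn2Cn < 0) {
    ddStop("copy numbers must be >= 0", "ddConfigError")
  }
  if (!qualified) {
    ddStop("unqualified samples are not classified for SMA",
           "ddPreconditionError")
  }
  if (smn1Cn == 0) {
    list(smaClass = "SMA_presumptive", needsSecondTier = TRUE)
  } else if (smn1Cn == 1) {
    list(smaClass = "Carrier", needsSecondTier = FALSE)
  } else {
    list(smaClass = "Normal", needsSecondTier = FALSE)
  }
}

#' Second-tier Sanger interpretation for presumptive SMA
#'
#' Decision table over the categorical outcomes of the two confirmatory
#' assays, applied only to first-tier presumptive SMA (SMN1 = 0) samples:
#'
#' * assay A `no_amplicon` + assay B `hom_c840T` — SMN1 exon 7 truly absent:
#'   `"SMA_confirmed"`.
#' * assay A shows an amplicon carrying a c.840 variant (`c840G` or
#'   `c840_other`) while assay B is heterozygous — the first-tier probe
#'   missed an intact SMN1 allele: `"Dropout_false_positive"`.
#' * anything else (e.g. assay A `c840C`, which contradicts the first tier):
#'   `"Review"`.
#'
#' @param firstTier first-tier class; must be `"SMA_presumptive"`.
#' @param outcome a [SangerOutcome-class].
#' @return the updated SMA class.
#' @examples
#' interpretSecondTier("SMA_presumptive", SangerOutcome("no_amplicon", "hom_c840T"))
#' interpretSecondTier("SMA_presumptive", SangerOutcome("c840G", "het_G_T"))
#' @export
interpretSecondTier <- function(firstTier, outcome) {
  if (!identical(firstTier, "SMA_presumptive")) {
    ddStop("second-tier interpretation applies only to presumptive SMA samples",
           "ddPreconditionError")
  }
  stopifnot(is(outcome, "SangerOutcome"))
  a <- outcome@assayA
  b <- outcome@assayB
  if (a == "no_amplicon" && b == "hom_c840T") {
    "SMA_confirmed"
  } else if (a %in% c("c840G", "c840_other") && b %in% c("het_C_T", "het_G_T")) {
    "Dropout_false_positive"
  } else {
    "Review"
  }
}

#' Screen one specimen
#'
#' Composes qualification, TREC classification, SMA classification and — when
#' the sample is presumptive SMA and a Sanger outcome is supplied —
#' second-tier interpretation into a single deterministic decision.
#'
#' Samples below the validated gestational age (default 34 weeks) are
#' classified against the same TREC cutoff but flagged
#' `"preterm_cutoff_not_validated"`; carriers receive a
#' `"carrier_compound_het_advisory"` flag (one-copy SMN1 newborns can carry a
#' point mutation on the remaining allele, which screening cannot see).
#'
#' @param quant a [WellQuant-class] from a QC-passed well.
#' @param cutoffs a [ScreenCutoffs-class].
#' @param secondTier optional [SangerOutcome-class].
#' @param gestationalAgeWeeks optional gestational age, weeks.
#' @return a [ScreenResult-class].
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 5000L)
#' w <- simulateWell(SampleTruth(trecBlood = 300), cfg, seed = 5)
#' screenSample(quantifyWell(callWell(w, cfg, overrideQC = TRUE), cfg))
#' @export
screenSample <- function(quant, cutoffs = ScreenCutoffs(), secondTier = NULL,
                         gestationalAgeWeeks = NA_real_) {
  rpp30 <- bloodConcentration(quant, "RPP30")
  trec <- bloodConcentration(quant, "TREC")
  smn1 <- targetRow(quant, "SMN1")$cnInteger
  smn2 <- targetRow(quant, "SMN2")$cnInteger
  qualified <- qualifySample(rpp30, cutoffs)
  trecClass <- classifyTrec(trec, rpp30, cutoffs)
  flags <- character()
  if (!is.na(gestationalAgeWeeks) &&
      gestationalAgeWeeks < cutoffs@minGestationalWeeks) {
    flags <- c(flags, "preterm_cutoff_not_validated")
  }
  smaClass <- NA_character_
  needsSecondTier <- FALSE
  if (qualified) {
    sm <- classifySmn(smn1, smn2, qualified)
    smaClass <- sm$smaClass
    needsSecondTier <- sm$needsSecondTier
    if (identical(smaClass, "Carrier")) {
      flags <- c(flags, "carrier_compound_het_advisory")
    }
    if (needsSecondTier && !is.null(secondTier)) {
      smaClass <- interpretSecondTier(smaClass, secondTier)
    }
  }
  new("ScreenResult",
    sampleId = quant@sampleId,
    qualified = qualified,
    trecClass = trecClass,
    smaClass = smaClass,
    smn1Cn = if (is.na(smn1)) NA_integer_ else as.integer(smn1),
    smn2Cn = if (is.na(smn2)) NA_integer_ else as.integer(smn2),
    needsSecondTier = needsSecondTier,
    flags = flags
  )
}
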