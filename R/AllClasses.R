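#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Assay configuration for the quadruplex ddPCR screen
#'
#' Holds the physical constants of the assay (droplet volume, droplet count,
#' reaction and specimen volumes), the target-to-channel assignment, and the
#' fluorescence cluster model used by the simulator.
#'
#' The volume constants drive the blood-unit conversion
#' \deqn{c_{blood} = \frac{copies/well}{V_{input}} \times
#'       \frac{V_{elution}}{V_{blood}}}
#' with defaults well 20 µL, input DNA 8 µL, elution 50 µL and 3 µL blood per
#' 3.2 mm dried-blood-spot punch. Channel assignment follows the quadruplex
#' assay: SMN1 on channel 1 (FAM), RPP30 on channel 2 (HEX), SMN2 on channel 3
#' (Cy5), TREC on channel 4 (Cy5.5).
#'
#' @slot dropletVolume droplet volume in nL (default 0.85, QX-series nominal).
#' @slot dropletsPerWell droplets generated per well (default 20000).
#' @slot wellVolume reaction volume loaded per well, µL (default 20).
#' @slot inputDnaVolume DNA volume in the reaction, µL (default 8).
#' @slot elutionVolume DNA elution volume, µL (default 50).
#' @slot bloodPerPunch blood content of one punch, µL (default 3).
#' @slot channelMap named integer vector target -> channel index.
#' @slot negMean,negSd,posMean,posSd per-channel Gaussian cluster parameters
#'   (arbitrary fluorescence units), length 4 in channel order.
#' @slot rainFraction proportion of template-positive droplets whose amplitude
#'   falls between the clusters ("rain").
#' @slot falsePositiveRate per-droplet probability that a template-free
#'   droplet shows a positive-cluster amplitude.
#' @slot runEffectSd log-sd of an optional multiplicative between-run loading
#'   effect (0 disables it; pure-Poisson mode).
#' @slot seed default RNG seed used by the simulators (NA = leave RNG alone).
#'
#' @seealso [simulateWell()], [quantifyWell()]
#' @export
setClass("AssayConfig",
  representation(
    dropletVolume = "numeric",
    dropletsPerWell = "integer",
    wellVolume = "numeric",
    inputDnaVolume = "numeric",
    elutionVolume = "numeric",
    bloodPerPunch = "numeric",
    channelMap = "integer",
    negMean = "numeric",
    negSd = "numeric",
    posMean = "numeric",
    posSd = "numeric",
    rainFraction = "numeric",
    falsePositiveRate = "numeric",
    runEffectSd = "numeric",
    seed = "integer"
  )
)

setValidity("AssayConfig", function(object) {
  msg <- character()
  vols <- c(
    dropletVolume = object@dropletVolume,
    wellVolume = object@wellVolume,
    inputDnaVolume = object@inputDnaVolume,
    elutionVolume = object@elutionVolume,
    bloodPerPunch = object@bloodPerPunch
  )
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    msg <- c(msg, "all volumes must be finite and > 0")
  }
  if (object@dropletsPerWell <= 0L) {
    msg <- c(msg, "dropletsPerWell must be > 0")
  }
  if (!identical(sort(names(object@channelMap)), sort(ddTargets())) ||
      !setequal(object@channelMap, 1:4)) {
    msg <- c(msg, "channelMap must map SMN1, RPP30, SMN2, TREC onto channels 1:4")
  }
  for (s in c("negMean", "negSd", "posMean", "posSd")) {
    if (length(slot(object, s)) != 4L) msg <- c(msg, paste(s, "must have length 4"))
  }
  if (length(object@posMean) == 4L && length(object@negMean) == 4L &&
      any(object@posMean <= object@negMean)) {
    msg <- c(msg, "posMean must exceed negMean in every channel")
  }
  if (object@rainFraction < 0 || object@rainFraction >= 0.5) {
    msg <- c(msg, "rainFraction must be in [0, 0.5)")
  }
  if (object@falsePositiveRate < 0 || object@falsePositiveRate >= 1) {
    msg <- c(msg, "falsePositiveRate must be in [0, 1)")
  }
  if (object@runEffectSd < 0) msg <- c(msg, "runEffectSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AssayConfig
#'
#' @param dropletVolume droplet volume, nL.
#' @param dropletsPerWell droplets per well.
#' @param wellVolume,inputDnaVolume,elutionVolume,bloodPerPunch volumes in µL.
#' @param channelMap named integer vector target -> channel.
#' @param negMean,negSd,posMean,posSd per-channel cluster parameters.
#' @param rainFraction,falsePositiveRate,runEffectSd simulator noise knobs.
#' @param seed default simulator seed (NA = none).
#' @return an [AssayConfig-class] object.
#' @examples
#' cfg <- AssayConfig()
#' bloodToCopiesPerWell(2500, cfg)
#' @export
AssayConfig <- function(dropletVolume = 0.85,
                        dropletsPerWell = 20000L,
                        wellVolume = 20,
                        inputDnaVolume = 8,
                        elutionVolume = 50,
                        bloodPerPunch = 3,
                        channelMap = c(SMN1 = 1L, RPP30 = 2L, SMN2 = 3L, TREC = 4L),
                        negMean = rep(1000, 4),
                        negSd = rep(150, 4),
                        posMean = rep(9000, 4),
                        posSd = rep(300, 4),
                        rainFraction = 0.01,
                        falsePositiveRate = 0,
                        runEffectSd = 0,
                        seed = NA_integer_) {
  new("AssayConfig",
    dropletVolume = as.numeric(dropletVolume),
    dropletsPerWell = as.integer(dropletsPerWell),
    wellVolume = as.numeric(wellVolume),
    inputDnaVolume = as.numeric(inputDnaVolume),
    elutionVolume = as.numeric(elutionVolume),
    bloodPerPunch = as.numeric(bloodPerPunch),
    channelMap = structure(as.integer(channelMap), names = names(channelMap)),
    negMean = as.numeric(negMean), negSd = as.numeric(negSd),
    posMean = as.numeric(posMean), posSd = as.numeric(posSd),
    rainFraction = as.numeric(rainFraction),
    falsePositiveRate = as.numeric(falsePositiveRate),
    runEffectSd = as.numeric(runEffectSd),
    seed = as.integer(seed)
  )
}

#' Ground-truth description of one specimen
#'
#' The simulator's truth record: per-genome SMN1/SMN2 copy numbers, TREC and
#' RPP30 blood concentrations, gestational age, and the specimen role. RPP30
#' is carried at two copies per genome, so the implied SMN1 blood
#' concentration is `rpp30Blood * smn1Cn / 2` (likewise SMN2).
#'
#' @slot smn1Cn,smn2Cn integer copies per genome.
#' @slot trecBlood,rpp30Blood copies/µL blood.
#' @slot gestationalAgeWeeks gestational age in weeks.
#' @slot role one of `"newborn"`, `"blank"`, `"proficiency"`, `"patient"`.
#' @slot sampleId specimen identifier.
#' @export
setClass("SampleTruth",
  representation(
    smn1Cn = "integer", smn2Cn = "integer",
    trecBlood = "numeric", rpp30Blood = "numeric",
    gestationalAgeWeeks = "numeric", role = "character",
    sampleId = "character"
  )
)

setValidity("SampleTruth", function(object) {
  msg <- character()
  if (object@smn1Cn < 0L || object@smn2Cn < 0L) {
    msg <- c(msg, "copy numbers must be >= 0")
  }
  if (object@trecBlood < 0 || object@rpp30Blood < 0) {
    msg <- c(msg, "blood concentrations must be >= 0")
  }
  if (!object@role %in% c("newborn", "blank", "proficiency", "patient")) {
    msg <- c(msg, "role must be newborn, blank, proficiency or patient")
  }
  if (object@role == "blank" &&
      (object@smn1Cn != 0L || object@smn2Cn != 0L ||
       object@trecBlood != 0 || object@rpp30Blood != 0)) {
    msg <- c(msg, "a blank specimen must have all targets at 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleTruth
#'
#' @param smn1Cn,smn2Cn integer copies per genome.
#' @param trecBlood,rpp30Blood copies/µL blood.
#' @param gestationalAgeWeeks gestational age, weeks.
#' @param role specimen role (`"newborn"`, `"blank"`, `"proficiency"`,
#'   `"patient"`).
#' @param sampleId specimen identifier.
#' @return a [SampleTruth-class] object.
#' @examples
#' SampleTruth(smn1Cn = 2, smn2Cn = 1, trecBlood = 300, rpp30Blood = 12000)
#' blankTruth()
#' @export
SampleTruth <- function(smn1Cn = 2L, smn2Cn = 2L, trecBlood = 180,
                        rpp30Blood = 15000, gestationalAgeWeeks = 39,
                        role = "newborn", sampleId = "sample1") {
  new("SampleTruth",
    smn1Cn = as.integer(smn1Cn), smn2Cn = as.integer(smn2Cn),
    trecBlood = as.numeric(trecBlood), rpp30Blood = as.numeric(rpp30Blood),
    gestationalAgeWeeks = as.numeric(gestationalAgeWeeks),
    role = role, sampleId = sampleId
  )
}

#' @rdname SampleTruth
#' @export
blankTruth <- function(sampleId = "blank1") {
  SampleTruth(
    smn1Cn = 0L, smn2Cn = 0L, trecBlood = 0, rpp30Blood = 0,
    role = "blank", sampleId = sampleId
  )
}

#' Per-droplet amplitudes for one well
#'
#' One row per accepted droplet, one column per fluorescence channel
#' (1 = FAM/SMN1, 2 = HEX/RPP30, 3 = Cy5/SMN2, 4 = Cy5.5/TREC). Simulator
#' output additionally carries a logical matrix of the same shape recording
#' which droplets truly contain template (`truthLabels`).
#'
#' @slot amplitudes numeric matrix, droplets x 4 channels.
#' @slot truthLabels logical matrix of the same shape, or NULL.
#' @slot sampleId,wellId,runId identifiers.
#' @export
setClass("DropletWell",
  representation(
    amplitudes = "matrix",
    truthLabels = "matrixOrNULL",
    sampleId = "character",
    wellId = "character",
    runId = "character"
  )
)

setValidity("DropletWell", function(object) {
  msg <- character()
  if (ncol(object@amplitudes) != 4L) {
    msg <- c(msg, "amplitudes must have 4 channel columns")
  }
  if (!is.null(object@truthLabels) &&
      !identical(dim(object@truthLabels), dim(object@amplitudes))) {
    msg <- c(msg, "truthLabels must have the same shape as amplitudes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DropletWell
#'
#' @param amplitudes numeric matrix, droplets x 4 channels.
#' @param truthLabels optional logical matrix of identical shape.
#' @param sampleId,wellId,runId identifiers.
#' @return a [DropletWell-class] object.
#' @export
DropletWell <- function(amplitudes, truthLabels = NULL, sampleId = "sample1",
                        wellId = "A01", runId = "run1") {
  colnames(amplitudes) <- paste0("ch", 1:4)
  new("DropletWell",
    amplitudes = amplitudes, truthLabels = truthLabels,
    sampleId = sampleId, wellId = wellId, runId = runId
  )
}

#' Per-well quantification result
#'
#' One row per target with Poisson rate (copies per droplet), reaction
#' concentration (copies/µL), copies per well, blood concentration
#' (copies/µL blood), and — for SMN1/SMN2 — the RPP30-referenced copy number
#' in raw, one-decimal and integer form, plus a 95% confidence interval on the
#' reaction concentration.
#'
#' @slot wellId,sampleId identifiers.
#' @slot quant data.frame with one row per target.
#' @slot flags character vector of quality flags (e.g. `"no_reference"`).
#' @export
setClass("WellQuant",
  representation(
    wellId = "character",
    sampleId = "character",
    quant = "data.frame",
    flags = "character"
  )
)

setValidity("WellQuant", function(object) {
  need <- c(
    "target", "nPositive", "nNegative", "lambda", "concReaction",
    "copiesPerWell", "concBlood", "cn", "cnReported", "cnInteger",
    "ciLow", "ciHigh"
  )
  if (!all(need %in% names(object@quant))) {
    return(paste(
      "quant must contain columns:",
      paste(setdiff(need, names(object@quant)), collapse = ", ")
    ))
  }
  TRUE
})

#' Screening decision cutoffs
#'
#' @slot rpp30MinBlood minimum RPP30 loading for a qualified sample,
#'   copies/µL blood (default 4200; comparison is strict `>`).
#' @slot trecCutoffBlood TREC screening cutoff, copies/µL blood (default 57,
#'   the 2.5th percentile of the full-term reference cohort; strict `>` is
#'   normal).
#' @slot minGestationalWeeks gestational age below which the TREC cutoff is
#'   not validated (default 34 weeks).
#' @export
setClass("ScreenCutoffs",
  representation(
    rpp30MinBlood = "numeric",
    trecCutoffBlood = "numeric",
    minGestationalWeeks = "numeric"
  )
)

setValidity("ScreenCutoffs", function(object) {
  if (object@rpp30MinBlood <= 0 || object@trecCutoffBlood <= 0 ||
      object@minGestationalWeeks <= 0) {
    return("all cutoffs must be > 0")
  }
  TRUE
})

#' Construct screening cutoffs
#'
#' @param rpp30MinBlood RPP30 qualification cutoff, copies/µL blood.
#' @param trecCutoffBlood TREC screening cutoff, copies/µL blood.
#' @param minGestationalWeeks minimum validated gestational age, weeks.
#' @return a [ScreenCutoffs-class] object.
#' @examples
#' ScreenCutoffs()
#' @export
ScreenCutoffs <- function(rpp30MinBlood = 4200, trecCutoffBlood = 57,
                          minGestationalWeeks = 34) {
  new("ScreenCutoffs",
    rpp30MinBlood = rpp30MinBlood, trecCutoffBlood = trecCutoffBlood,
    minGestationalWeeks = minGestationalWeeks
  )
}

#' Second-tier Sanger sequencing outcome
#'
#' Categorical results of the two confirmatory Sanger assays run on
#' first-tier SMN1-absent samples. Assay A is SMN1-specific (primers on
#' c.835-44G>A and c.888+100A>G, discriminating nucleotides other than
#' c.840); assay B amplifies both SMN1 and SMN2 across c.840.
#'
#' @slot assayA one of `"no_amplicon"`, `"c840C"`, `"c840G"`, `"c840_other"`.
#' @slot assayB one of `"hom_c840T"`, `"hom_c840C"`, `"het_C_T"`,
#'   `"het_G_T"`, `"other"`.
#' @export
setClass("SangerOutcome",
  representation(assayA = "character", assayB = "character")
)

.assayALevels <- c("no_amplicon", "c840C", "c840G", "c840_other")
.assayBLevels <- c("hom_c840T", "hom_c840C", "het_C_T", "het_G_T", "other")

setValidity("SangerOutcome", function(object) {
  msg <- character()
  if (!object@assayA %in% .assayALevels) {
    msg <- c(msg, paste("assayA must be one of:", paste(.assayALevels, collapse = ", ")))
  }
  if (!object@assayB %in% .assayBLevels) {
    msg <- c(msg, paste("assayB must be one of:", paste(.assayBLevels, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SangerOutcome
#'
#' @param assayA SMN1-specific assay result.
#' @param assayB non-specific (SMN1+SMN2) assay result.
#' @return a [SangerOutcome-class] object.
#' @examples
#' SangerOutcome("no_amplicon", "hom_c840T") # homozygous SMN1 deletion
#' @export
SangerOutcome <- function(assayA, assayB) {
  new("SangerOutcome", assayA = assayA, assayB = assayB)
}

.trecLevels <- c("Negative", "Positive", "Unqualified")
.smaLevels <- c(
  "Normal", "Carrier", "SMA_presumptive", "SMA_confirmed",
  "Dropout_false_positive", "Review"
)

#' Screening result for one specimen
#'
#' @slot sampleId specimen identifier.
#' @slot qualified logical; RPP30 loading above the qualification cutoff.
#' @slot trecClass `"Negative"`, `"Positive"` (screen positive, below
#'   cutoff — triggers re-punch/retest/recall) or `"Unqualified"`.
#' @slot smaClass `"Normal"`, `"Carrier"`, `"SMA_presumptive"`,
#'   `"SMA_confirmed"`, `"Dropout_false_positive"`, `"Review"`, or NA for
#'   unqualified samples.
#' @slot smn1Cn,smn2Cn integer copy-number calls.
#' @slot needsSecondTier logical; TRUE for qualified SMN1 = 0 samples.
#' @slot flags character advisory flags (e.g. `"preterm_cutoff_not_validated"`,
#'   `"carrier_compound_het_advisory"`).
#' @export
setClass("ScreenResult",
  representation(
    sampleId = "character",
    qualified = "logical",
    trecClass = "character",
    smaClass = "character",
    smn1Cn = "integer",
    smn2Cn = "integer",
    needsSecondTier = "logical",
    flags = "character"
  )
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (!object@trecClass %in% .trecLevels) {
    msg <- c(msg, "invalid trecClass")
  }
  if (!is.na(object@smaClass) && !object@smaClass %in% .smaLevels) {
    msg <- c(msg, "invalid smaClass")
  }
  if (identical(object@trecClass, "Unqualified") == object@qualified) {
    msg <- c(msg, "trecClass Unqualified must coincide with qualified = FALSE")
  }
  if (length(msg)) msg else TRUE
})
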