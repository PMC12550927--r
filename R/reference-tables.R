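#' Bundled proficiency-testing and accuracy specimen tables
#'
#' Published specimen-level results distributed with the package for worked
#' examples and for validating the screening decision engine against external
#' quality-assessment classifications.
#'
#' `trecProficiencySpecimens()` returns the ten CDC NSQAP TRECPT
#' proficiency specimens: measured TREC and RPP30 blood concentrations with
#' the program's reference classification.
#'
#' `smnAccuracySpecimens()` returns the eleven SMN accuracy specimens: five
#' NSQAP SMN1 exon 7 specimens (one-decimal first-tier copy-number results
#' and the program classification) and six SMA patient specimens
#' (MLPA-confirmed copy numbers, first-tier copy-number results, and the
#' categorical outcomes of the two second-tier Sanger assays).
#'
#' `cohortCopyNumberCounts()` returns the SMN1/SMN2 integer copy-number
#' counts observed in a screening cohort of 1867 newborn samples.
#'
#' @return a data.frame (see Details).
#' @name reference-tables
#' @examples
#' trecProficiencySpecimens()
NULL

#' @rdname reference-tables
#' @export
trecProficiencySpecimens <- function() {
  data.frame(
    specimen = 1:10,
    trecBlood = c(326, 130, 141, 168, 0, 0, 0, 0, 0, 0),
    rpp30Blood = c(10932, 14472, 15927, 9998, 144892, 122741, 120351, 73699, 0, 4),
    referenceClass = c(
      rep("Negative", 4), rep("Positive", 4), rep("Unqualified", 2)
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference-tables
#' @export
smnAccuracySpecimens <- function() {
  nsqap <- data.frame(
    specimen = paste0("NSQAP", 1:5),
    group = "proficiency",
    smn1CnReported = c(2.0, 0.0, 0.9, 0.0, 0.9),
    smn2CnReported = c(1.0, 1.9, 1.9, 1.9, 1.9),
    referenceClass = c("Normal", "SMA", "Carrier", "SMA", "Carrier"),
    assayA = NA_character_,
    assayB = NA_character_,
    stringsAsFactors = FALSE
  )
  patients <- data.frame(
    specimen = paste0("patient", 1:6),
    group = "patient",
    smn1CnReported = rep(0.0, 6),
    smn2CnReported = c(2.0, 2.0, 3.0, 3.1, 4.0, 4.0),
    referenceClass = "SMA", # MLPA-confirmed 0 SMN1 copies
    assayA = "no_amplicon", # "no peak"
    assayB = "hom_c840T",
    stringsAsFactors = FALSE
  )
  rbind(nsqap, patients)
}

#' @rdname reference-tables
#' @export
cohortCopyNumberCounts <- function() {
  data.frame(
    target = c(rep("SMN1", 5), rep("SMN2", 7)),
    copyNumber = c(1:5, 0:6),
    count = c(43, 1707, 111, 4, 2, 90, 669, 1040, 57, 5, 5, 1),
    stringsAsFactors = FALSE
  )
}
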