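Package: ddScreen
Title: Quadruplex Droplet Digital PCR Newborn Screening for SMA and SCID
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a fully automated quadruplex
    droplet digital PCR (ddPCR) newborn-screening computation for spinal
    muscular atrophy (SMA) and severe combined immunodeficiency (SCID).
    Converts per-droplet fluorescence amplitudes into per-channel
    positive/negative calls by a lowest-density-valley threshold, performs
    Poisson absolute quantification, computes RPP30-referenced SMN1/SMN2
    copy numbers and TREC/RPP30 blood concentrations, applies the screening
    decision rules (sample qualification, TREC classification, SMA/carrier
    classification, second-tier Sanger allele-dropout exclusion), and
    provides assay-validation statistics (precision, LoB/LoD/LoQ,
    linearity, reference intervals, Levey-Jennings QC, stability recovery).
    A synthetic droplet generator emulates quadruplex wells, replicate
    series, blanks, dilution series and screening cohorts so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'reference-tables.R'
    'simulate.R'
    'calling.R'
    'quantify.R'
    'screening.R'
    'validation.R'
    'io.R'
    'pipeline.R'
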