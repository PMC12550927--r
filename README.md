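# ddScreen

Quadruplex droplet digital PCR (ddPCR) newborn screening for spinal
muscular atrophy (SMA) and severe combined immunodeficiency (SCID), as a
tested R pipeline: from per-droplet fluorescence amplitudes to *SMN1*/*SMN2*
copy-number calls, TREC/*RPP30* blood concentrations, screening
classifications (including second-tier Sanger allele-dropout exclusion),
and the assay-validation statistics a clinical laboratory reports. A
synthetic droplet generator emulates quadruplex wells so every stage is
testable without instrument data.

It is written for laboratory scientists and bioinformaticians who run or
evaluate DBS-based SMA/SCID screening and want the downstream computation —
normally locked inside vendor software — open, scriptable and testable.

## The model

One well partitions a 20 µL reaction into ~20,000 droplets of volume *v*.
For a target at reaction concentration *c*, copies per droplet are Poisson
with mean λ = *c·v*, so the negative-droplet fraction estimates e^−λ and

    λ̂ = −ln(n_neg / N),    ĉ = λ̂ / v .

Droplets are called positive/negative per channel by a threshold at the
amplitude of lowest droplet density between the two clusters; wells with
fewer than 10,000 accepted droplets are excluded. Copy number is referenced
to *RPP30* at two copies per genome, CN = 2·c_target / c_RPP30, and blood
units follow

    copies/µL blood = (copies per 20 µL well / 8 µL input DNA)
                      × (50 µL elution / 3 µL blood per punch) ,

so the recommended 100–5000 copies/µL reaction loading window maps to
4167–≈208,300 copies/µL blood. Screening rules: *RPP30* > 4200 copies/µL
blood qualifies a sample; TREC > 57 copies/µL blood is screen-negative;
integer *SMN1* CN 0 / 1 / ≥2 is presumptive SMA / carrier / normal, and
presumptive SMA is confirmed or cleared by a second-tier Sanger decision
table targeting discriminating nucleotides away from c.840.

## Worked example

Simulate a carrier newborn (1 × *SMN1*, 2 × *SMN2*, TREC 250 copies/µL
blood, *RPP30* 12,000 copies/µL blood), call, quantify and screen it:

```r
library(ddScreen)
cfg   <- AssayConfig()
truth <- SampleTruth(smn1Cn = 1L, smn2Cn = 2L, trecBlood = 250,
                     rpp30Blood = 12000, sampleId = "NB0001")
well  <- simulateWell(truth, cfg, seed = 8)
calls <- callWell(well, cfg)
quant <- quantifyWell(calls, cfg)
quant
#> WellQuant for well A01
#>  target nPositive nNegative concReaction concBlood cnReported
#>    SMN1      2302     17698     143.8600      5994        1.0
#>   RPP30      4436     15564     295.0300     12293        2.0
#>    SMN2      4312     15688     285.6900     11904        1.9
#>    TREC       104     19896       6.1336       256         NA
screenSample(quant, ScreenCutoffs())
#> ScreenResult for NB0001
#>  qualified: TRUE
#>  TREC: Negative | SMA: Carrier
#>  SMN1 CN: 1 | SMN2 CN: 2 | second tier needed: FALSE
#>  flags: carrier_compound_het_advisory
```

Reading the output: each row is one fluorescence channel. The measured
blood concentrations (12,293 for *RPP30*, 256 for TREC) recover the
simulated truth within Poisson counting noise; *SMN1* at half the *RPP30*
concentration gives copy number 1.0 — a carrier. The sample qualifies
(*RPP30* > 4200), screens TREC-negative (256 > 57), and carries the
advisory that a one-copy *SMN1* result cannot exclude a point mutation on
the remaining allele.

`runPipeline()` applies the same chain to a whole plate (with per-well QC
logging and TSV/CSV reports), and `inst/scripts/ddscreen.R` wraps it for
the shell. Validation statistics live in `computeCV()`, `limitOfBlank()`,
`limitOfDetection()`, `limitOfQuantification()`, `linearityFit()`,
`referenceInterval()`, `leveyJenningsFlags()`, `stabilityRecovery()` and
`cnDistributionTable()`.

## Package layout

* `R/simulate.R` — synthetic well / replicate / dilution / cohort generator
* `R/calling.R` — density-valley thresholding and well QC
* `R/quantify.R` — Poisson quantification, copy number, unit conversion
* `R/screening.R` — qualification, TREC and SMA rules, second-tier table
* `R/validation.R` — CV, LoB/LoD/LoQ, linearity, reference interval, QC
  charts, stability, distribution tables
* `R/io.R`, `R/pipeline.R` — CSV/TSV/YAML interchange and the plate pipeline
* `vignettes/ddscreen-methods.Rmd` — the methods account: model,
  assumptions, parameter choices, and what simulation can and cannot show
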