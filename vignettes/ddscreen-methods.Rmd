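---
title: "Methods: quadruplex ddPCR newborn screening for SMA and SCID"
author: "ddScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadruplex ddPCR newborn screening for SMA and SCID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddScreen)
```

## The screening problem

Newborn screening for spinal muscular atrophy (SMA) and severe combined
immunodeficiency (SCID) can share one quadruplex droplet digital PCR (ddPCR)
reaction on DNA from a dried-blood-spot (DBS) punch. Four targets are
measured at once: *SMN1* (homozygous exon 7 deletion causes SMA), *SMN2*
(copy number modifies SMA severity and guides treatment), TREC (T-cell
receptor excision circles; low levels indicate the T-cell lymphopenia of
SCID), and *RPP30* (a two-copies-per-genome reference that doubles as a
DNA-quantity control). ddScreen implements the full downstream computation:
per-droplet fluorescence → positive/negative droplet calls → Poisson
absolute quantification → copy numbers and blood-unit concentrations →
screening classifications, plus the assay-validation statistics a clinical
laboratory reports, and a synthetic droplet generator so that every stage is
testable without an instrument.

## Droplet statistics

Partitioning a reaction into droplets turns quantification into counting.
If a well has $N$ droplets of volume $v$ and the target concentration in the
reaction is $c$, the copies per droplet are Poisson with mean
$\lambda = c\,v$, so the fraction of *negative* droplets estimates
$e^{-\lambda}$ and

$$\hat\lambda = -\ln\frac{n_{neg}}{N}, \qquad
  \hat c = \frac{\hat\lambda}{v}.$$

`poissonConcentration()` implements this with a normal-approximation
confidence interval on the log scale,
$\mathrm{var}(\hat\lambda) \approx (1-p_{neg})/(N\,p_{neg})$ — standard
digital-PCR practice; an exact binomial interval would change nothing
material at $N = 20{,}000$. Saturation ($n_{neg}=0$) is an error, not a
number.

Copy number is referenced to *RPP30* fixed at two copies per genome:
$\mathrm{CN} = 2\,c_{target}/c_{RPP30}$. The ratio cancels the droplet
volume, so CN is robust to the one physical constant the instrument vendor
does not publish. Reported CN is rounded half-up to one decimal (matching
how such tables are printed); the integer call is the nearest integer with
ties rounded up — no integerisation convention is published for the vendor
software, so this choice is ours and is applied consistently.

## Blood-unit conversion

Concentrations are reported per µL of blood, not per µL of reaction:

$$\text{copies/µL blood} =
  \frac{\text{copies per 20 µL well}}{8\ \text{µL input DNA}} \times
  \frac{V_{elution}}{3\ \text{µL blood per punch}}.$$

The default elution volume is 50 µL. A 15 µL value also circulates for this
assay family, but only 50 µL reproduces the recommended-loading anchors
(100 copies/µL reaction → 4167 copies/µL blood; 5000 → ≈208,300) and matches
the 50 µL DBS extraction protocol; both are supported via
`AssayConfig(elutionVolume = )`, with 50 as the default because it is the
value the printed anchors are consistent with.

## Threshold selection

The positive/negative threshold per channel is placed at the amplitude of
lowest droplet density between the two clusters. `estimateThreshold()`
builds a 256-bin histogram, smooths it with a 5-bin moving average, finds
local maxima above 1% of the peak density, takes the two tallest as the
cluster modes, and returns the density minimum strictly between them. Two
guards matter in practice:

* **Valley depth.** Sampling noise on a *single* Gaussian cluster produces
  many shallow local maxima; a "valley" is only accepted if its density is
  below half the smaller mode's density. Genuine ddPCR clusters are
  separated by a nearly empty region, so this never rejects a real valley.
* **Single-mode fallbacks.** A channel with no positives (blank, or the
  *SMN1* channel of an SMA sample) has one mode at the negative level; the
  threshold is then mode + 7·MAD (`fallback_no_positive`) — far enough that
  Gaussian tails at 20,000 droplets/well essentially never cross it, close
  enough that any true positive at the configured positive-cluster level is
  counted. If the single mode sits high (clusters merged), the midpoint of
  the configured cluster means is used (`fallback_midpoint`).

Rain droplets (between the clusters) follow whichever side of the threshold
they land on; no separate rain class is kept, since the reference behaviour
of vendor software is unpublished.

Wells with fewer than 10,000 accepted droplets are excluded by `qcWell()`
("fewer than 10,000 excluded" is read literally, so exactly 10,000 passes).

## Decision rules

With cutoffs `ScreenCutoffs()` (all comparisons strict, as the source
decision tables print them):

* **Qualification:** *RPP30* > 4200 copies/µL blood. Below that, too little
  DNA was loaded and the sample is *Unqualified* — never classified further.
* **TREC:** > 57 copies/µL blood is Negative (normal); otherwise Positive,
  a flag standing in for the operational re-punch/retest/recall loop.
  The 57 is the 2.5th percentile of a full-term reference cohort; samples
  under 34 weeks gestation are classified against the same cutoff but
  flagged `preterm_cutoff_not_validated`.
* **SMA:** integer *SMN1* CN 0 → presumptive SMA (second tier required);
  1 → Carrier (with a compound-heterozygote advisory — a point mutation on
  the remaining allele is invisible to this screen); ≥2 → Normal.
* **Second tier:** presumptive SMA samples get two Sanger assays. Assay A
  amplifies only *SMN1*, via discriminating nucleotides *away* from c.840
  (c.835-44G>A, c.888+100A>G); assay B amplifies both genes across c.840.
  True homozygous deletion: A has no amplicon, B shows homozygous c.840T
  (from *SMN2*) → confirmed. Allele dropout at c.840 (e.g. c.840C>G under
  the first-tier probe): A amplifies and shows the variant, B is
  heterozygous → false positive, cleared. Any other combination —
  including assay A showing normal c.840C, which contradicts the first
  tier — is escalated for manual review rather than forced into a class.

`screenSample()` composes these deterministically; `runPipeline()` applies
them to a plate.

## The synthetic-data generator

`simulateWell()` emulates what the instrument does between the reaction and
the amplitude table:

1. Expected copies per well are obtained by inverting the blood-unit
   conversion (same constants, guaranteeing round-trip consistency).
2. The number of molecules captured in droplets is Poisson with mean scaled
   by the sampled fraction $N v / V_{well}$ (0.85 at the defaults: 20,000 ×
   0.85 nL droplets sample 17 of the 20 µL reaction); they are assigned to
   droplets uniformly at random — the multinomial partition that produces
   Poisson occupancy.
3. Amplitudes are Gaussian per cluster (defaults: negative 1000 ± 150,
   positive 9000 ± 300 arbitrary units, well separated as in real 2D
   cluster plots). **Rain** replaces the amplitude of a fraction (default
   1%) of *template-positive* droplets with a uniform draw between the
   cluster means: rain is partial amplification, so template-free droplets
   never rain — which is also the only model consistent with blank wells
   measuring exactly zero. A configurable per-droplet false-positive rate
   (default 0) can place template-free droplets in the positive cluster.
4. Per-droplet, per-channel template occupancy is recorded as
   `truthLabels`, the oracle used by the calling tests.

Droplet volume (0.85 nL) and count (20,000) are instrument-typical
constants, not published for this assay; both are configurable and copy
numbers do not depend on them.

`simulateReplicates()` adds an optional lognormal between-run loading factor
(`runEffectSd`, default 0 = pure Poisson) so between-run CV can exceed
within-run CV as on a real bench. `simulateDilutionSeries()` reproduces the
linearity design: two-fold levels from a top concentration, default 8 levels
× 5 replicates from 2500 down to ≈19.5 TREC copies/µL blood.
`simulateCohort()` draws screening cohorts: integer copy numbers from the
bundled 1867-sample frequency table, TREC lognormal with median 180
copies/µL blood and log-sd $\ln(180/57)/1.96 \approx 0.586$ (chosen so the
2.5th percentile sits at the 57 cutoff — only that percentile is published,
the shape is a stand-in), RPP30 loadings lognormal with median 15,000
copies/µL blood and log-sd 0.4 (spanning the observed 4–145k range of
proficiency specimens), and a preterm fraction defaulting to 55/1867.
Cohort droplet wells are generated only on request; truth tables suffice for
distribution and reference-interval analyses and a full 1867-well cohort of
amplitudes would be gigabytes.

What the simulator deliberately does **not** model: PCR amplification
kinetics, droplet volume dispersion, channel crosstalk, instrument optics.
Consequently, passing tests demonstrate the correctness of the *computation*
(thresholding, Poisson estimation, conversion, decision logic) under
idealised noise — they do not certify performance on real instrument data,
whose bench-level CVs, LoD and LoQ embed wet-lab noise this generator has no
claim to reproduce.

## Validation statistics

* `computeCV()` — sample SD (n−1), CV = 100·SD/mean; at a true level of 0
  the CV is undefined and the absolute SD is reported instead.
* `limitOfBlank()` — nonparametric 95th percentile of ≥20 blanks, rank
  $(n+1)p$ with linear interpolation (reduces to 0 when all blanks are 0).
* `limitOfDetection()` — LoB + 1.6 × SD of a low-level sample. The 1.6
  multiplier is kept verbatim (the common CLSI value is 1.645); no silent
  correction.
* `limitOfQuantification()` — lowest level with replicate CV < 25%.
* `linearityFit()` — OLS of measured on expected with $R^2$.
* `referenceInterval()` — $(n+1)p$ percentile after excluding samples
  < 34 weeks; fewer than 120 eligible samples flags the estimate
  unreliable.
* `leveyJenningsFlags()` — the ±2 SD acceptance rule, with consecutive
  same-side violations reported as a 2-2s advisory (full multirule QC is
  out of scope).
* `stabilityRecovery()` — 100 × mean(day N)/mean(day 0), pass within
  90–110%.
* `cnDistributionTable()` — counts and half-up one-decimal percentages.

## Numerical choices and degenerate inputs

* Rounding is half-up throughout reporting (`roundHalfUp()`), because
  banker's rounding would print x.x5 boundaries differently than clinical
  tables do; full precision is kept in all serialized numeric tables,
  display rounding happens only in the human-facing report.
* Percentile convention is $(n+1)p$ with linear interpolation everywhere a
  percentile is taken, and is recorded in the output method string.
* Ties among density modes break toward the lower amplitude; the valley is
  the first minimum-density bin between the modes.
* Degenerate inputs are errors with distinct condition classes
  (`ddSaturationError`, `ddNoReferenceError`, `ddInsufficientDataError`,
  `ddSchemaError`, `ddConfigError`, `ddQCError`, `ddPreconditionError`),
  never silent NAs — except the blank-well copy number, which is NA with a
  `no_reference` flag so that the well's zero concentrations remain
  reportable while screening correctly treats the sample as unqualified.
* A load above 10 expected copies per droplet is rejected as saturating
  (virtually every droplet occupied; the negative fraction unmeasurable).

## Problem sizes

The test-suite and acceptance computations use the study's own designs where
they are desk-scale: 20 replicate wells for within-run precision, 25 (5 × 5)
for between-run, 8 × 5 wells for linearity, 20 blanks for LoB — all at the
default 20,000 droplets per well. Module unit tests use 500–5000-droplet
wells (with QC overridden) to keep the suite fast; Monte-Carlo consistency
checks use 10,000–100,000 draws. Cohort-scale claims that depend on real
newborn populations (the 57 copies/µL cutoff itself, bench CVs, TREC
LoD = 3 and LoQ = 29 copies/µL blood) are not reproducible from simulation
and are covered instead by formula-level unit tests and
parameter-recovery/property suites.

## Known limitations

* One threshold per channel: no 2D/4D cluster assignment, no crosstalk
  compensation, no probabilistic rain handling.
* The decision engine represents the retest/recall workflow as flags, not a
  workflow engine; borderline-TREC replicate policy is a flag only.
* Partial intragenic *SMN2* deletions, hybrid *SMN1/SMN2* genes and point
  mutations are invisible to copy-number screening by design; carriers get
  an advisory flag, nothing more.
* Second-tier interpretation is a decision table over declared categorical
  Sanger outcomes; chromatogram base-calling is out of scope.
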