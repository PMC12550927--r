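# Shared fixtures: a small-well config keeps module tests fast; acceptance
# checks use the default 20,000-droplet configuration.

smallCfg <- function(n = 2000L, ...) {
  AssayConfig(dropletsPerWell = as.integer(n), ...)
}

# quantify a simulated well end to end (QC overridden for small wells)
quantifySim <- function(well, cfg) {
  quantifyWell(callWell(well, cfg, overrideQC = TRUE), cfg)
}

# blood concentration giving an expected per-droplet occupancy lambda:
# lambda = concBlood * (input * blood/punch / elution) * dropletVolume[uL]
#          / wellVolume
concForLambda <- function(lambda, cfg) {
  perWell <- lambda * cfg@wellVolume / (cfg@dropletVolume * 1e-3)
  perWell / (cfg@inputDnaVolume * cfg@bloodPerPunch / cfg@elutionVolume)
}

typicalTruth <- function(...) {
  SampleTruth(smn1Cn = 2L, smn2Cn = 2L, trecBlood = 300, rpp30Blood = 12000, ...)
}
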