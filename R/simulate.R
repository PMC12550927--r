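# Synthetic quadruplex ddPCR well generator. Template molecules are drawn
# Poisson at the expected copies-per-well implied by the truth record and the
# volume constants, assigned uniformly at random to droplets (the multinomial
# partition the instrument performs), and fluorescence amplitudes drawn from
# per-channel Gaussian clusters.

#' Expected copies per well implied by a blood concentration
#'
#' Inverts the blood-unit conversion of [toBloodConcentration()]: with the
#' default volumes, copies/well = copies/µL blood x 8/1 x 3/50 = 0.48 x
#' copies/µL blood, guaranteeing round-trip consistency between simulation
#' and quantification.
#'
#' @param concBlood copies/µL blood.
#' @param cfg an [AssayConfig-class].
#' @return expected template copies in one well.
#' @export
bloodToCopiesPerWell <- function(concBlood, cfg = AssayConfig()) {
  concBlood * cfg@inputDnaVolume * cfg@bloodPerPunch / cfg@elutionVolume
}

# per-target blood concentrations implied by a truth record; RPP30 carries
# two copies per genome so SMN targets scale as cn/2
truthBloodConcentrations <- function(truth) {
  c(
    SMN1 = truth@rpp30Blood * truth@smn1Cn / 2,
    RPP30 = truth@rpp30Blood,
    SMN2 = truth@rpp30Blood * truth@smn2Cn / 2,
    TREC = truth@trecBlood
  )
}

# core well draw; never touches the RNG seed (wrappers seed once at entry)
.simulateWellCore <- function(truth, cfg, loadingFactor = 1, sampleId = NULL,
                              wellId = "A01", runId = "run1") {
  n <- cfg@dropletsPerWell
  concs <- truthBloodConcentrations(truth) * loadingFactor
  expWell <- bloodToCopiesPerWell(concs, cfg)
  # droplets sample only n x dropletVolume of the reaction (17 of 20 uL at
  # the defaults); molecules outside that volume are never partitioned
  sampledFraction <- n * cfg@dropletVolume * 1e-3 / cfg@wellVolume
  # beyond ~10 copies per droplet essentially every droplet is occupied and
  # the negative fraction is unmeasurable
  if (any(expWell * sampledFraction > 10 * n)) {
    ddStop(
      sprintf(
        "expected load (%.3g copies/well) saturates the partition: more than 10 expected copies per droplet",
        max(expWell)
      ),
      "ddSaturationError"
    )
  }
  amps <- matrix(NA_real_, nrow = n, ncol = 4,
                 dimnames = list(NULL, paste0("ch", 1:4)))
  labels <- matrix(FALSE, nrow = n, ncol = 4)
  for (target in ddTargets()) {
    ch <- cfg@channelMap[[target]]
    m <- stats::rpois(1L, expWell[[target]] * sampledFraction)
    occupied <- logical(n)
    if (m > 0L) {
      counts <- tabulate(sample.int(n, m, replace = TRUE), nbins = n)
      occupied <- counts > 0L
    }
    labels[, ch] <- occupied
    amp <- stats::rnorm(n, cfg@negMean[ch], cfg@negSd[ch])
    nPos <- sum(occupied)
    if (nPos > 0L) {
      amp[occupied] <- stats::rnorm(nPos, cfg@posMean[ch], cfg@posSd[ch])
      # rain: partially amplified template-positive droplets falling between
      # the clusters; template-free droplets never rain, so blanks stay blank
      if (cfg@rainFraction > 0) {
        rainy <- occupied & (stats::runif(n) < cfg@rainFraction)
        nr <- sum(rainy)
        if (nr > 0L) {
          amp[rainy] <- stats::runif(nr, cfg@negMean[ch], cfg@posMean[ch])
        }
      }
    }
    if (cfg@falsePositiveRate > 0) {
      fp <- !occupied & (stats::runif(n) < cfg@falsePositiveRate)
      nf <- sum(fp)
      if (nf > 0L) {
        amp[fp] <- stats::rnorm(nf, cfg@posMean[ch], cfg@posSd[ch])
      }
    }
    amps[, ch] <- amp
  }
  DropletWell(
    amplitudes = amps, truthLabels = labels,
    sampleId = if (is.null(sampleId)) truth@sampleId else sampleId,
    wellId = wellId, runId = runId
  )
}

#' Simulate one quadruplex ddPCR well
#'
#' Draws the template molecules captured in droplets per target
#' Poisson-distributed around the expected copies-per-well implied by `truth`
#' and the volume constants, scaled by the fraction of the reaction the
#' droplets sample (`dropletsPerWell * dropletVolume / wellVolume`, 0.85 at
#' the defaults), partitions them uniformly into droplets, and emits per-droplet
#' fluorescence amplitudes from the configured negative/positive Gaussian
#' clusters, with optional rain (template-positive droplets with intermediate
#' amplitude) and false-positive droplets. Ground-truth occupancy is recorded
#' in `truthLabels`.
#'
#' @param truth a [SampleTruth-class].
#' @param cfg an [AssayConfig-class].
#' @param seed RNG seed; `NA` (default `cfg@seed`) leaves the RNG stream
#'   untouched. The same seed reproduces the well exactly.
#' @param wellId,runId identifiers stamped on the well.
#' @return a [DropletWell-class].
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 5000L)
#' w <- simulateWell(SampleTruth(trecBlood = 300), cfg, seed = 7)
#' acceptedEvents(w)
#' @export
simulateWell <- function(truth, cfg = AssayConfig(), seed = cfg@seed,
                         wellId = "A01", runId = "run1") {
  if (!is.na(seed)) set.seed(seed)
  .simulateWellCore(truth, cfg, wellId = wellId, runId = runId)
}

#' Simulate replicate wells within and across runs
#'
#' Emits `nWithin` wells per run across `nRuns` runs (e.g. 20 x 1 for
#' within-run precision, 5 x 5 for between-run precision). When
#' `cfg@runEffectSd > 0` each run receives a lognormal multiplicative loading
#' factor so between-run variation exceeds within-run variation; the default
#' 0 is pure-Poisson mode.
#'
#' @inheritParams simulateWell
#' @param nWithin wells per run (>= 1).
#' @param nRuns number of runs (>= 1).
#' @return list of [DropletWell-class], with `runId` of the form `"runK"`.
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 2000L)
#' reps <- simulateReplicates(SampleTruth(), cfg, nWithin = 5, nRuns = 5, seed = 1)
#' table(vapply(reps, function(w) w@runId, ""))
#' @export
simulateReplicates <- function(truth, cfg = AssayConfig(), nWithin = 20,
                               nRuns = 1, seed = cfg@seed) {
  if (nWithin < 1 || nRuns < 1) {
    ddStop("nWithin and nRuns must be >= 1", "ddConfigError")
  }
  if (!is.na(seed)) set.seed(seed)
  wells <- vector("list", nWithin * nRuns)
  k <- 0L
  for (r in seq_len(nRuns)) {
    loading <- if (cfg@runEffectSd > 0) stats::rlnorm(1L, 0, cfg@runEffectSd) else 1
    for (i in seq_len(nWithin)) {
      k <- k + 1L
      wells[[k]] <- .simulateWellCore(
        truth, cfg,
        loadingFactor = loading,
        wellId = sprintf("R%02dW%02d", r, i), runId = paste0("run", r)
      )
    }
  }
  wells
}

#' Simulate a two-fold dilution series
#'
#' Generates `levels` two-fold dilution levels from `topBloodConc` down
#' (level k expects `topBloodConc / 2^(k-1)` copies/µL blood), each measured
#' in `replicates` wells — the standard linearity design of eight levels from
#' 2500 down to ~20 TREC copies/µL blood, five replicates each. RPP30 is held
#' at a constant background so wells remain quantifiable.
#'
#' @inheritParams simulateWell
#' @param topBloodConc highest expected TREC concentration, copies/µL blood.
#' @param levels number of two-fold levels (>= 2).
#' @param replicates wells per level (>= 1).
#' @param rpp30Blood constant RPP30 background, copies/µL blood.
#' @return data.frame with columns `level`, `expectedBlood`, `replicate` and
#'   a list-column `well` of [DropletWell-class] objects.
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 2000L)
#' ser <- simulateDilutionSeries(100, levels = 2, replicates = 1, cfg, seed = 3)
#' ser$expectedBlood
#' @export
simulateDilutionSeries <- function(topBloodConc, levels = 8, replicates = 5,
                                   cfg = AssayConfig(), seed = cfg@seed,
                                   rpp30Blood = 12000) {
  if (levels < 2 || replicates < 1 || topBloodConc <= 0) {
    ddStop("need levels >= 2, replicates >= 1, topBloodConc > 0", "ddConfigError")
  }
  if (!is.na(seed)) set.seed(seed)
  expected <- topBloodConc / 2^(seq_len(levels) - 1)
  out <- expand.grid(replicate = seq_len(replicates), level = seq_len(levels))
  out <- out[order(out$level, out$replicate), c("level", "replicate")]
  out$expectedBlood <- expected[out$level]
  wells <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    truth <- SampleTruth(
      smn1Cn = 2L, smn2Cn = 2L, trecBlood = out$expectedBlood[i],
      rpp30Blood = rpp30Blood, role = "newborn",
      sampleId = sprintf("L%02dR%02d", out$level[i], out$replicate[i])
    )
    wells[[i]] <- .simulateWellCore(
      truth, cfg,
      wellId = sprintf("L%02dR%02d", out$level[i], out$replicate[i])
    )
  }
  out$well <- wells
  rownames(out) <- NULL
  out
}

# default integer copy-number frequencies for a newborn screening cohort,
# derived from the bundled 1867-sample distribution table
defaultCnFrequencies <- function() {
  counts <- cohortCopyNumberCounts()
  split_ <- split(counts, counts$target)
  lapply(split_, function(d) {
    structure(d$count / sum(d$count), names = as.character(d$copyNumber))
  })
}

#' Simulate a newborn-screening cohort
#'
#' Draws per-sample SMN1/SMN2 integer copy numbers from the supplied
#' frequency tables (default: the bundled 1867-sample screening
#' distribution), TREC blood concentrations from a lognormal model (default
#' median 180 copies/µL blood with log-sd such that the 2.5th percentile sits
#' near 57), RPP30 loadings from a lognormal spanning the typical
#' dried-blood-spot range, and gestational ages with a configurable preterm
#' (<34 weeks) fraction.
#'
#' Droplet wells are only simulated when `simulateWells = TRUE`; the default
#' returns the truth table alone, which is what reference-interval and
#' distribution analyses consume.
#'
#' @inheritParams simulateWell
#' @param n cohort size (0 gives an empty cohort).
#' @param cnFrequencies named list with elements `SMN1` and `SMN2`, each a
#'   named proportion vector over integer copy numbers summing to 1.
#' @param trecMeanlog,trecSdlog lognormal parameters of the TREC model.
#' @param rpp30Meanlog,rpp30Sdlog lognormal parameters of the RPP30 loading.
#' @param pretermFraction expected fraction of samples <34 weeks gestation.
#' @param simulateWells also generate a [DropletWell-class] per sample.
#' @return list with `truth` (data.frame: sampleId, smn1Cn, smn2Cn,
#'   trecBlood, rpp30Blood, gestationalAgeWeeks, role) and `wells` (list or
#'   NULL).
#' @examples
#' coh <- simulateCohort(100, seed = 11)
#' table(coh$truth$smn1Cn)
#' @export
simulateCohort <- function(n, cnFrequencies = defaultCnFrequencies(),
                           trecMeanlog = log(180),
                           trecSdlog = log(180 / 57) / stats::qnorm(0.975),
                           rpp30Meanlog = log(15000), rpp30Sdlog = 0.4,
                           pretermFraction = 55 / 1867,
                           cfg = AssayConfig(), seed = cfg@seed,
                           simulateWells = FALSE) {
  for (tg in c("SMN1", "SMN2")) {
    fr <- cnFrequencies[[tg]]
    if (is.null(fr) || abs(sum(fr) - 1) > 1e-9) {
      ddStop(
        sprintf("cnFrequencies$%s must sum to 1", tg), "ddConfigError"
      )
    }
  }
  if (!is.na(seed)) set.seed(seed)
  if (n == 0) {
    return(list(
      truth = data.frame(
        sampleId = character(), smn1Cn = integer(), smn2Cn = integer(),
        trecBlood = numeric(), rpp30Blood = numeric(),
        gestationalAgeWeeks = numeric(), role = character()
      ),
      wells = if (simulateWells) list() else NULL
    ))
  }
  drawCn <- function(fr) {
    as.integer(sample(as.integer(names(fr)), n, replace = TRUE, prob = fr))
  }
  smn1 <- drawCn(cnFrequencies$SMN1)
  smn2 <- drawCn(cnFrequencies$SMN2)
  trec <- stats::rlnorm(n, trecMeanlog, trecSdlog)
  rpp30 <- stats::rlnorm(n, rpp30Meanlog, rpp30Sdlog)
  preterm <- stats::runif(n) < pretermFraction
  # full-term ages 37-42 weeks; preterm 28-33.9 weeks
  ga <- ifelse(preterm, stats::runif(n, 28, 34), stats::runif(n, 37, 42))
  truth <- data.frame(
    sampleId = sprintf("S%05d", seq_len(n)),
    smn1Cn = smn1, smn2Cn = smn2,
    trecBlood = trec, rpp30Blood = rpp30,
    gestationalAgeWeeks = ga, role = "newborn",
    stringsAsFactors = FALSE
  )
  wells <- NULL
  if (simulateWells) {
    wells <- vector("list", n)
    for (i in seq_len(n)) {
      st <- SampleTruth(
        smn1Cn = smn1[i], smn2Cn = smn2[i], trecBlood = trec[i],
        rpp30Blood = rpp30[i], gestationalAgeWeeks = ga[i],
        role = "newborn", sampleId = truth$sampleId[i]
      )
      wells[[i]] <- .simulateWellCore(st, cfg, wellId = truth$sampleId[i])
    }
  }
  list(truth = truth, wells = wells)
}
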