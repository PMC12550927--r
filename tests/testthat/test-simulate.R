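test_that("blank wells with no false positives contain no template in any channel", {
  cfg <- smallCfg(falsePositiveRate = 0)
  w <- simulateWell(blankTruth(), cfg, seed = 1)
  expect_equal(acceptedEvents(w), 2000L)
  expect_true(all(colSums(truthLabels(w)) == 0))
  # all amplitudes sit in the negative cluster
  expect_true(all(amplitudes(w) < 2500))
})

test_that("occupancy follows Poisson statistics: P(positive) = 1 - exp(-lambda)", {
  cfg <- AssayConfig(dropletsPerWell = 20000L, rainFraction = 0)
  for (lambda in c(log(2), 0.1, 1)) {
    truth <- SampleTruth(
      smn1Cn = 0L, smn2Cn = 0L, trecBlood = 0,
      rpp30Blood = concForLambda(lambda, cfg)
    )
    w <- simulateWell(truth, cfg, seed = round(100 * lambda))
    pExp <- 1 - exp(-lambda)
    pObs <- mean(truthLabels(w)[, 2]) # RPP30 channel
    tol <- 3 * sqrt(pExp * (1 - pExp) / 20000)
    expect_lt(abs(pObs - pExp), tol)
  }
})

test_that("the same seed reproduces a well exactly and different seeds do not", {
  cfg <- smallCfg()
  w1 <- simulateWell(typicalTruth(), cfg, seed = 42)
  w2 <- simulateWell(typicalTruth(), cfg, seed = 42)
  w3 <- simulateWell(typicalTruth(), cfg, seed = 43)
  expect_identical(amplitudes(w1), amplitudes(w2))
  expect_identical(truthLabels(w1), truthLabels(w2))
  expect_false(identical(amplitudes(w1), amplitudes(w3)))
})

test_that("saturating loads are rejected", {
  cfg <- smallCfg()
  hot <- SampleTruth(rpp30Blood = concForLambda(1, cfg) * 1e4)
  expect_error(simulateWell(hot, cfg, seed = 1), class = "ddSaturationError")
})

test_that("replicate series have the requested well and run structure", {
  cfg <- smallCfg()
  within <- simulateReplicates(typicalTruth(), cfg, nWithin = 20, nRuns = 1, seed = 2)
  expect_length(within, 20)
  expect_length(unique(vapply(within, function(w) w@runId, "")), 1L)

  between <- simulateReplicates(typicalTruth(), cfg, nWithin = 5, nRuns = 5, seed = 2)
  expect_length(between, 25)
  expect_length(unique(vapply(between, function(w) w@runId, "")), 5L)

  # degenerate series reproduces a single simulateWell draw at the same seed
  single <- simulateReplicates(typicalTruth(), cfg, nWithin = 1, nRuns = 1, seed = 9)
  direct <- simulateWell(typicalTruth(), cfg, seed = 9)
  expect_identical(amplitudes(single[[1]]), amplitudes(direct))
})

test_that("between-run loading effects widen run-to-run spread when enabled", {
  cfg <- smallCfg(runEffectSd = 0.2)
  reps <- simulateReplicates(typicalTruth(), cfg, nWithin = 2, nRuns = 4, seed = 3)
  runPos <- vapply(reps, function(w) sum(truthLabels(w)[, 2]), numeric(1))
  runs <- vapply(reps, function(w) w@runId, "")
  # same-run wells share one loading factor, so run means differ
  expect_gt(stats::sd(tapply(runPos, runs, mean)), 0)
})

test_that("dilution series halve the expected concentration per level", {
  cfg <- smallCfg()
  ser <- simulateDilutionSeries(2500, levels = 8, replicates = 5, cfg, seed = 4)
  expect_equal(nrow(ser), 40)
  expect_equal(sort(unique(ser$expectedBlood)), sort(2500 / 2^(0:7)))
  expect_equal(min(ser$expectedBlood), 2500 / 128) # ~19.5 copies/uL blood

  two <- simulateDilutionSeries(100, levels = 2, replicates = 1, cfg, seed = 4)
  expect_equal(two$expectedBlood, c(100, 50))

  serA <- simulateDilutionSeries(2500, 8, 5, cfg, seed = 6)
  serB <- simulateDilutionSeries(2500, 8, 5, cfg, seed = 6)
  expect_identical(
    lapply(serA$well, amplitudes), lapply(serB$well, amplitudes)
  )
})

test_that("cohorts reproduce the configured copy-number frequencies", {
  empty <- simulateCohort(0, seed = 1)
  expect_equal(nrow(empty$truth), 0)

  bad <- list(SMN1 = c(`2` = 0.5), SMN2 = c(`2` = 1))
  expect_error(simulateCohort(10, cnFrequencies = bad, seed = 1),
               class = "ddConfigError")

  # expected one-copy SMN1 count at the screening-cohort frequency
  coh <- simulateCohort(1867, seed = 10)
  oneCopy <- sum(coh$truth$smn1Cn == 1)
  ci <- stats::qbinom(c(0.025, 0.975), 1867, 43 / 1867)
  expect_gte(oneCopy, ci[1])
  expect_lte(oneCopy, ci[2])

  # goodness of fit of SMN2 frequencies at large n
  big <- simulateCohort(100000, seed = 12)
  fr <- cohortCopyNumberCounts()
  fr <- fr[fr$target == "SMN2", ]
  obs <- table(factor(big$truth$smn2Cn, levels = fr$copyNumber))
  gof <- stats::chisq.test(as.integer(obs), p = fr$count / sum(fr$count))
  expect_gt(gof$p.value, 0.001)

  # identical seed => identical cohort
  coh2 <- simulateCohort(1867, seed = 10)
  expect_identical(coh$truth, coh2$truth)
})

test_that("cohort gestational ages respect the preterm fraction", {
  coh <- simulateCohort(20000, pretermFraction = 0.1, seed = 21)
  pObs <- mean(coh$truth$gestationalAgeWeeks < 34)
  expect_lt(abs(pObs - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("cohort TREC model places its 2.5th percentile near the screening cutoff", {
  coh <- simulateCohort(50000, seed = 33)
  q <- unname(stats::quantile(coh$truth$trecBlood, 0.025))
  expect_lt(abs(q - 57) / 57, 0.05)
})
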