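test_that("Poisson concentration matches the closed form", {
  z <- poissonConcentration(0, 20000, 0.85)
  expect_equal(z$lambda, 0)
  expect_equal(z$concReaction, 0)

  half <- poissonConcentration(10000, 20000, 0.85)
  expect_equal(half$lambda, log(2))
  expect_equal(half$concReaction, log(2) / 0.85e-3, tolerance = 1e-12)
  expect_equal(round(half$concReaction, 2), 815.47)
  expect_true(half$ci[1] < half$concReaction & half$concReaction < half$ci[2])

  expect_error(poissonConcentration(20000, 20000, 0.85),
               class = "ddSaturationError")
})

test_that("Poisson concentration agrees with a Monte-Carlo partitioning oracle", {
  # oracle: partition M molecules into N droplets uniformly, count occupied
  set.seed(77)
  N <- 5000L
  M <- 3000L
  occ <- replicate(200, sum(tabulate(sample.int(N, M, replace = TRUE), N) > 0))
  lamHat <- mean(vapply(occ, function(p) poissonConcentration(p, N, 0.85)$lambda,
                        numeric(1)))
  expect_lt(abs(lamHat - M / N) / (M / N), 0.02)
})

test_that("concentration is strictly monotone in the positive count", {
  conc <- vapply(c(10, 100, 1000, 5000, 15000), function(p) {
    poissonConcentration(p, 20000, 0.85)$concReaction
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("copy number is referenced to RPP30 at two copies per genome", {
  expect_equal(copyNumber(100, 100)$cn, 2)
  expect_equal(copyNumber(100, 100)$cnInteger, 2L)

  zero <- copyNumber(0, 100)
  expect_equal(zero$cnReported, 0)
  expect_equal(zero$cnInteger, 0L)

  carrier <- copyNumber(0.47 * 100, 100)
  expect_equal(carrier$cn, 0.94)
  expect_equal(carrier$cnReported, 0.9)
  expect_equal(carrier$cnInteger, 1L)

  # mid-integer ties round up
  expect_equal(copyNumber(0.75 * 100, 100)$cnInteger, 2L)
  expect_error(copyNumber(10, 0), class = "ddNoReferenceError")
})

test_that("blood-unit conversion reproduces the recommended loading window", {
  # 100 copies/uL reaction = 2000 copies per 20 uL well
  expect_equal(toBloodConcentration(2000), 12500 / 3, tolerance = 1e-12)
  expect_equal(round(toBloodConcentration(2000)), 4167)
  # 5000 copies/uL reaction
  expect_equal(round(toBloodConcentration(100000)), 208333)
  expect_equal(toBloodConcentration(0), 0)
  # 15 uL elution variant scales by 15/50
  cfg15 <- AssayConfig(elutionVolume = 15)
  expect_equal(toBloodConcentration(2000, cfg15), 1250, tolerance = 1e-12)
})

test_that("quantified wells recover simulated truth concentrations", {
  cfg <- AssayConfig(dropletsPerWell = 20000L)
  truth <- typicalTruth()
  w <- simulateWell(truth, cfg, seed = 19)
  q <- quantifySim(w, cfg)
  tab <- quantTable(q)

  # Poisson CV of a concentration estimate: sqrt(exp(lambda) - 1) /
  # (lambda * sqrt(N))
  cvPoisson <- function(lambda, n) sqrt(exp(lambda) - 1) / (lambda * sqrt(n))
  for (tg in c("RPP30", "TREC")) {
    expected <- if (tg == "TREC") truth@trecBlood else truth@rpp30Blood
    row <- tab[tab$target == tg, ]
    cv <- cvPoisson(row$lambda, 20000)
    expect_lt(abs(row$concBlood - expected) / expected, 3 * cv)
  }
  expect_equal(tab$cnReported[tab$target == "SMN1"], 2, tolerance = 0.051)
  expect_equal(tab$cn[tab$target == "RPP30"], 2)
})

test_that("SMA-pattern wells quantify to zero SMN1 with intact SMN2", {
  cfg <- AssayConfig(dropletsPerWell = 20000L)
  truth <- SampleTruth(smn1Cn = 0L, smn2Cn = 3L, trecBlood = 300,
                       rpp30Blood = 12000)
  q <- quantifySim(simulateWell(truth, cfg, seed = 20), cfg)
  tab <- quantTable(q)
  expect_equal(tab$cnReported[tab$target == "SMN1"], 0)
  expect_equal(tab$cn[tab$target == "SMN2"], 3, tolerance = 0.15)
})

test_that("blank wells quantify to zero and flag the missing reference", {
  cfg <- smallCfg()
  q <- quantifySim(simulateWell(blankTruth(), cfg, seed = 21), cfg)
  expect_true(all(quantTable(q)$concBlood == 0))
  expect_true("no_reference" %in% q@flags)
  expect_true(all(is.na(quantTable(q)$cn[quantTable(q)$target %in% c("SMN1", "SMN2")])))
})

test_that("copy number is invariant to droplet volume and consistent volume scaling", {
  mkCalls <- function() data.frame(
    wellId = "w", sampleId = "s", channel = 1:4,
    target = c("SMN1", "RPP30", "SMN2", "TREC"),
    threshold = 5000,
    nPositive = c(4000, 4000, 6000, 100),
    nNegative = c(16000, 16000, 14000, 19900),
    method = "valley", qcPass = TRUE, stringsAsFactors = FALSE
  )
  q1 <- quantifyWell(mkCalls(), AssayConfig(dropletVolume = 0.85))
  q2 <- quantifyWell(mkCalls(), AssayConfig(dropletVolume = 1.2))
  expect_equal(quantTable(q1)$cn, quantTable(q2)$cn)

  # doubling all conversion volumes leaves cn unchanged (ratio cancels)
  q3 <- quantifyWell(mkCalls(), AssayConfig(
    inputDnaVolume = 16, elutionVolume = 100, bloodPerPunch = 6
  ))
  expect_equal(quantTable(q1)$cn, quantTable(q3)$cn)
})

test_that("round-trip truth recovery tightens with replication", {
  cfg <- smallCfg(5000L)
  truth <- typicalTruth()
  reps <- simulateReplicates(truth, cfg, nWithin = 10, nRuns = 1, seed = 23)
  rpp <- vapply(reps, function(w) {
    bloodConcentration(quantifySim(w, cfg), "RPP30")
  }, numeric(1))
  lam <- truth@rpp30Blood * 0.48 * cfg@dropletVolume * 1e-3 / cfg@wellVolume
  cvP <- sqrt(exp(lam) - 1) / (lam * sqrt(5000))
  seMean <- cvP / sqrt(10)
  expect_lt(abs(mean(rpp) - truth@rpp30Blood) / truth@rpp30Blood, 3 * seMean)
})
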