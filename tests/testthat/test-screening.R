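test_that("sample qualification uses a strict RPP30 cutoff", {
  expect_true(qualifySample(10932))
  expect_false(qualifySample(4))
  expect_false(qualifySample(4200)) # boundary: strict >
  expect_true(qualifySample(4200.1))
})

test_that("TREC classification follows the qualification-then-cutoff rule", {
  expect_identical(classifyTrec(326, 10932), "Negative")
  expect_identical(classifyTrec(0, 144892), "Positive")
  expect_identical(classifyTrec(0, 0), "Unqualified")
  expect_identical(classifyTrec(57, 10000), "Positive") # boundary: strict >
  expect_identical(classifyTrec(57.1, 10000), "Negative")
})

test_that("SMN classification maps integer copy numbers to screening classes", {
  expect_identical(classifySmn(2, 1)$smaClass, "Normal")
  sma <- classifySmn(0, 2)
  expect_identical(sma$smaClass, "SMA_presumptive")
  expect_true(sma$needsSecondTier)
  carrier <- classifySmn(1, 2)
  expect_identical(carrier$smaClass, "Carrier")
  expect_false(carrier$needsSecondTier)
  expect_identical(classifySmn(4, 0)$smaClass, "Normal")
  expect_error(classifySmn(2, 2, qualified = FALSE),
               class = "ddPreconditionError")
})

test_that("the second-tier decision table confirms, clears or escalates", {
  expect_identical(
    interpretSecondTier("SMA_presumptive", SangerOutcome("no_amplicon", "hom_c840T")),
    "SMA_confirmed"
  )
  expect_identical(
    interpretSecondTier("SMA_presumptive", SangerOutcome("c840G", "het_G_T")),
    "Dropout_false_positive"
  )
  # assay A shows normal SMN1 sequence: contradicts the first tier
  expect_identical(
    interpretSecondTier("SMA_presumptive", SangerOutcome("c840C", "het_C_T")),
    "Review"
  )
  expect_error(
    interpretSecondTier("Normal", SangerOutcome("no_amplicon", "hom_c840T")),
    class = "ddPreconditionError"
  )
  expect_error(SangerOutcome("bogus", "hom_c840T"))
})

mkQuant <- function(trecBlood, rpp30Blood, smn1 = 2L, smn2 = 2L,
                    sampleId = "s") {
  # WellQuant carrying given blood concentrations and integer CNs
  tab <- data.frame(
    target = c("SMN1", "RPP30", "SMN2", "TREC"),
    nPositive = 1, nNegative = 1, lambda = 0.1, concReaction = 1,
    copiesPerWell = 1,
    concBlood = c(rpp30Blood * smn1 / 2, rpp30Blood, rpp30Blood * smn2 / 2,
                  trecBlood),
    cn = c(smn1, 2, smn2, NA), cnReported = c(smn1, 2, smn2, NA),
    cnInteger = c(smn1, 2L, smn2, NA),
    ciLow = 0, ciHigh = 2, stringsAsFactors = FALSE
  )
  new("WellQuant", wellId = sampleId, sampleId = sampleId, quant = tab,
      flags = character())
}

test_that("screenSample composes the decision chain deterministically", {
  r <- screenSample(mkQuant(130, 14472))
  expect_true(r@qualified)
  expect_identical(r@trecClass, "Negative")
  expect_identical(r@smaClass, "Normal")

  blankish <- screenSample(mkQuant(0, 0, smn1 = NA_integer_, smn2 = NA_integer_))
  expect_false(blankish@qualified)
  expect_identical(blankish@trecClass, "Unqualified")
  expect_true(is.na(blankish@smaClass))

  pat5 <- screenSample(
    mkQuant(300, 12000, smn1 = 0L, smn2 = 4L),
    secondTier = SangerOutcome("no_amplicon", "hom_c840T")
  )
  expect_identical(pat5@smaClass, "SMA_confirmed")
  expect_equal(pat5@smn2Cn, 4L)
  expect_true(pat5@needsSecondTier)

  # pure function: identical inputs, identical result
  r2 <- screenSample(mkQuant(130, 14472))
  expect_identical(r@trecClass, r2@trecClass)
  expect_identical(r@smaClass, r2@smaClass)
})

test_that("all ten bundled proficiency specimens classify concordantly", {
  tab <- trecProficiencySpecimens()
  got <- mapply(classifyTrec, tab$trecBlood, tab$rpp30Blood)
  expect_identical(unname(got), tab$referenceClass)
})

test_that("the eleven bundled SMN accuracy specimens classify concordantly", {
  tab <- smnAccuracySpecimens()
  for (i in seq_len(nrow(tab))) {
    smn1 <- as.integer(roundHalfUp(tab$smn1CnReported[i]))
    cls <- classifySmn(smn1, as.integer(roundHalfUp(tab$smn2CnReported[i])))
    if (tab$group[i] == "patient") {
      expect_true(cls$needsSecondTier)
      final <- interpretSecondTier(
        cls$smaClass, SangerOutcome(tab$assayA[i], tab$assayB[i])
      )
      expect_identical(final, "SMA_confirmed")
    } else {
      mapped <- c(Normal = "Normal", Carrier = "Carrier",
                  SMA_presumptive = "SMA")[cls$smaClass]
      expect_identical(unname(mapped), tab$referenceClass[i])
    }
  }
})

test_that("no unqualified sample is ever assigned a Carrier or Normal class", {
  for (rpp in c(0, 4, 4200)) {
    r <- screenSample(mkQuant(100, rpp))
    expect_false(r@qualified)
    expect_true(is.na(r@smaClass))
    expect_identical(r@trecClass, "Unqualified")
  }
})

test_that("preterm samples are classified but flagged as outside validation", {
  r <- screenSample(mkQuant(30, 12000), gestationalAgeWeeks = 30)
  expect_identical(r@trecClass, "Positive")
  expect_true("preterm_cutoff_not_validated" %in% r@flags)
  full <- screenSample(mkQuant(30, 12000), gestationalAgeWeeks = 39)
  expect_false("preterm_cutoff_not_validated" %in% full@flags)
})

test_that("carriers carry the compound-heterozygote advisory flag", {
  r <- screenSample(mkQuant(300, 12000, smn1 = 1L, smn2 = 2L))
  expect_identical(r@smaClass, "Carrier")
  expect_true("carrier_compound_het_advisory" %in% r@flags)
})
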