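test_that("mechanism statements validate identifiers lexically", {
  mech <- lofMechanism()
  expect_s4_class(mech, "DiseaseMechanismStatement")
  expect_error(DiseaseMechanismStatement("gene1", "MONDO:0000001",
                                         "autosomal_recessive",
                                         "loss_of_function"), "HGNC")
  expect_error(DiseaseMechanismStatement("GENE1", "OMIM:123456",
                                         "autosomal_recessive",
                                         "loss_of_function"), "MONDO")
  expect_error(DiseaseMechanismStatement("GENE1", "MONDO:0000001",
                                         "somatic", "loss_of_function"),
               "modeOfInheritance")
  expect_error(DiseaseMechanismStatement("GENE1", "MONDO:0000001",
                                         "autosomal_recessive",
                                         "loss_of_function",
                                         pathways = "GO:12"), "GO")
})

test_that("assay-class applicability is gated by the probed mechanism", {
  mechLof <- lofMechanism()
  mechGof <- DiseaseMechanismStatement("GENE1", "MONDO:0000002",
                                       "autosomal_dominant",
                                       "gain_of_function")
  lofClass <- AssayClass("c1", "cellular",
                         mechanismsProbed = "loss_of_function")
  dualClass <- AssayClass("c2", "in_vitro",
                          mechanismsProbed = c("loss_of_function",
                                               "dominant_negative"))
  expect_true(assessApplicability(lofClass, mechLof)$applicable)
  expect_false(assessApplicability(lofClass, mechGof)$applicable)
  mechDn <- DiseaseMechanismStatement("GENE1", "MONDO:0000003",
                                      "autosomal_dominant",
                                      "dominant_negative")
  expect_true(assessApplicability(dualClass, mechDn)$applicable)
  expect_match(assessApplicability(lofClass, mechGof)$rationale,
               "not applicable")
})

test_that("missing experimental controls or replication means no evidence", {
  noNull <- AssayInstance("i1", "c1", hasNullControl = FALSE)
  expect_identical(assignValidationTier(noNull)$pathogenic, "none")
  noWt <- AssayInstance("i1", "c1", hasWildtypeControl = FALSE)
  expect_identical(assignValidationTier(noWt)$benign, "none")
  noReps <- AssayInstance("i1", "c1", hasTechnicalReplicates = FALSE,
                          hasBiologicalReplicates = FALSE)
  expect_identical(assignValidationTier(noReps)$pathogenic, "none")
  # one replicate type suffices
  oneRep <- AssayInstance("i1", "c1", hasTechnicalReplicates = FALSE)
  expect_identical(assignValidationTier(oneRep)$pathogenic, "supporting")
})

test_that("historical or kit-based assays reach supporting without documentation", {
  kit <- AssayInstance("i1", "c1", basis = "historical_or_kit",
                       hasWildtypeControl = FALSE, hasNullControl = FALSE,
                       hasTechnicalReplicates = FALSE,
                       hasBiologicalReplicates = FALSE)
  tiers <- assignValidationTier(kit)
  expect_identical(tiers$pathogenic, "supporting")
  expect_identical(tiers$benign, "supporting")
})

test_that("validation-control counts set the supporting/moderate boundary", {
  eight <- makeInstance(4, 4)        # 8 validation controls
  expect_identical(assignValidationTier(eight)$pathogenic, "supporting")
  expect_equal(assignValidationTier(eight)$nControls, 8L)
  eleven <- makeInstance(6, 5)       # 11 mixed controls, no formal statistics
  tiers <- assignValidationTier(eleven)
  expect_identical(tiers$pathogenic, "moderate")
  expect_identical(tiers$benign, "moderate")
})

test_that("a formal OddsPath sets the tier, capping the benign direction at strong", {
  strongP <- makeInstance(20, 5, formal = TRUE)   # OddsPath (20, 0.2)
  tiers <- assignValidationTier(strongP)
  expect_identical(tiers$pathogenic, "strong")
  expect_identical(tiers$benign, "moderate")
  strongB <- makeInstance(5, 25, formal = TRUE)   # OddsPath (5, 0.04)
  tiers <- assignValidationTier(strongB)
  expect_identical(tiers$benign, "strong")
  veryStrong <- makeInstance(400, 5, formal = TRUE)
  expect_identical(assignValidationTier(veryStrong)$pathogenic, "very_strong")
  expect_true(tierRank(assignValidationTier(veryStrong)$benign) <=
                tierRank("strong"))
})

test_that("tiers are monotone in validation-control counts", {
  prev <- -1L
  for (n in c(2, 4, 6, 10, 12, 16)) {
    inst <- makeInstance(ceiling(n / 2), floor(n / 2))
    now <- tierRank(assignValidationTier(inst)$pathogenic)
    expect_gte(now, prev)
    prev <- now
  }
  # removing experimental controls never raises a tier
  full <- makeInstance(6, 5)
  gutted <- full; gutted@hasNullControl <- FALSE
  expect_lte(tierRank(assignValidationTier(gutted)$pathogenic),
             tierRank(assignValidationTier(full)$pathogenic))
  # adding formal statistics never lowers a tier below the count-based one
  formal <- makeInstance(6, 5, formal = TRUE)
  expect_gte(tierRank(assignValidationTier(formal)$pathogenic),
             tierRank(assignValidationTier(makeInstance(6, 5))$pathogenic))
})
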