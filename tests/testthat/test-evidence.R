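mechLof <- lofMechanism()

test_that("abnormal, normal and indeterminate calls map to PS3/BS3/none", {
  inst <- makeInstance(6, 5)   # moderate ceiling
  abn <- applyEvidence(FunctionalCall("v1", "functionally_abnormal",
                                      "complete_loss_of_function"),
                       inst, mechLof)
  expect_identical(tierLabel(abn), "PS3_moderate")
  nrm <- applyEvidence(FunctionalCall("v1", "functionally_normal"),
                       inst, mechLof)
  expect_identical(tierLabel(nrm), "BS3_moderate")
  ind <- applyEvidence(FunctionalCall("v1", "indeterminate"), inst, mechLof)
  expect_identical(ind@code, "none")
  expect_match(ind@justification, "neither PS3 nor BS3")
})

test_that("hypomorphic results are downgraded one tier with a warning", {
  inst <- makeInstance(6, 5)
  app <- applyEvidence(FunctionalCall("v1", "functionally_abnormal",
                                      "partial_loss_of_function"),
                       inst, mechLof)
  expect_identical(tierLabel(app), "PS3_supporting")
  expect_match(paste(app@warnings, collapse = " "), "special consideration")
  # the downgrade is a configurable policy
  keep <- applyEvidence(FunctionalCall("v1", "functionally_abnormal",
                                       "partial_loss_of_function"),
                        inst, mechLof,
                        policy = evidencePolicy(hypomorphDowngrade = FALSE))
  expect_identical(tierLabel(keep), "PS3_moderate")
})

test_that("mechanism-inconsistent abnormal results are not applied", {
  inst <- makeInstance(6, 5)
  app <- applyEvidence(FunctionalCall("v1", "functionally_abnormal",
                                      "gain_of_function"),
                       inst, mechLof)
  expect_identical(app@code, "none")
  expect_match(app@justification, "not consistent")
  # unknown subtype defaults to compatible, with a warning
  unk <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"),
                       inst, mechLof)
  expect_identical(unk@code, "PS3")
  expect_match(paste(unk@warnings, collapse = " "), "not specified")
})

test_that("an inapplicable assay class blocks evidence application", {
  inst <- makeInstance(6, 5)
  gofClass <- AssayClass("c1", "cellular", mechanismsProbed = "gain_of_function")
  expect_error(applyEvidence(FunctionalCall("v1", "functionally_abnormal"),
                             inst, mechLof, assayClass = gofClass),
               "may not be applied")
})

test_that("single-domain assays attach a completeness warning to BS3", {
  inst <- makeInstance(6, 5)
  narrow <- AssayClass("c1", "in_vitro", mechanismsProbed = "loss_of_function",
                       probesFullFunction = FALSE)
  app <- applyEvidence(FunctionalCall("v1", "functionally_normal"),
                       inst, mechLof, assayClass = narrow)
  expect_identical(app@code, "BS3")
  expect_match(paste(app@warnings, collapse = " "), "less strong")
})

test_that("patient-derived evidence requires explicit acknowledgment", {
  inst <- makeInstance(6, 5)
  fc <- FunctionalCall("v1", "functionally_abnormal",
                       contextFlags = "patient_derived")
  expect_error(applyEvidence(fc, inst, mechLof), "PP4")
  ok <- applyEvidence(fc, inst, mechLof,
                      policy = evidencePolicy(acknowledgePatientDerived = TRUE))
  expect_identical(ok@code, "PS3")
  expect_match(paste(ok@warnings, collapse = " "), "unrelated individuals")
})

test_that("context warnings fire on their flags and only their flags", {
  w <- contextWarnings(FunctionalCall("v", "indeterminate",
                                      contextFlags = "patient_derived"))
  expect_match(paste(w, collapse = " "), "PP4")
  w <- contextWarnings(FunctionalCall("v", "indeterminate",
                                      contextFlags = c("cdna_construct",
                                                       "ptc_nmd_subject")))
  expect_match(paste(w, collapse = " "), "endogenous")
  # cDNA alone is fine for substitutions; no NMD warning
  expect_length(contextWarnings(FunctionalCall("v", "indeterminate",
                                               contextFlags = "cdna_construct")), 0)
  w <- contextWarnings(FunctionalCall("v", "indeterminate",
                                      contextFlags = "model_organism"))
  expect_match(paste(w, collapse = " "), "nuanced")
  w <- contextWarnings(FunctionalCall("v", "indeterminate",
                                      contextFlags = "splicing_assay"))
  expect_match(paste(w, collapse = " "), "splic")
  expect_length(contextWarnings(FunctionalCall("v", "indeterminate")), 0)
})

test_that("consistent results take the most-validated assay's strength", {
  weak <- makeInstance(4, 4, instanceId = "weak")            # supporting
  strong <- makeInstance(6, 5, instanceId = "strong")        # moderate
  instances <- list(weak = weak, strong = strong)
  a1 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), weak, mechLof)
  a2 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), strong, mechLof)
  out <- combineEvidence(list(a1, a2), instances)
  expect_identical(tierLabel(out), "PS3_moderate")
  expect_identical(out@instanceId, "strong")
})

test_that("conflicts resolve by validation or cancel when equal", {
  weak <- makeInstance(4, 4, instanceId = "weak")
  strong <- makeInstance(6, 5, instanceId = "strong")
  instances <- list(weak = weak, strong = strong)
  ps <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), weak, mechLof)
  bs <- applyEvidence(FunctionalCall("v1", "functionally_normal"), strong, mechLof)
  out <- combineEvidence(list(ps, bs), instances)
  expect_identical(out@code, "BS3")
  expect_identical(tierLabel(out), "BS3_moderate")
  # equal validation: conflicting evidence is not used
  strong2 <- makeInstance(6, 5, instanceId = "strong2", seed = 2L)
  instances2 <- list(strong = strong, strong2 = strong2)
  ps2 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), strong2, mechLof)
  none <- combineEvidence(list(ps2, bs), instances2)
  expect_identical(none@code, "none")
  expect_match(none@justification, "conflict")
})

test_that("cross-class stacking is off by default and opt-in", {
  i1 <- makeInstance(4, 4, instanceId = "i1", classId = "classA")
  i2 <- makeInstance(4, 4, instanceId = "i2", classId = "classB", seed = 2L)
  instances <- list(i1 = i1, i2 = i2)
  a1 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), i1, mechLof)
  a2 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), i2, mechLof)
  default <- combineEvidence(list(a1, a2), instances)
  expect_identical(tierLabel(default), "PS3_supporting")
  stacked <- combineEvidence(list(a1, a2), instances,
                             policy = evidencePolicy(allowCrossClassStacking = TRUE))
  expect_identical(tierLabel(stacked), "PS3_moderate")
  expect_match(paste(stacked@warnings, collapse = " "), "double-counting")
})

test_that("combineEvidence is order-invariant and idempotent", {
  weak <- makeInstance(4, 4, instanceId = "weak")
  strong <- makeInstance(6, 5, instanceId = "strong")
  instances <- list(weak = weak, strong = strong)
  a1 <- applyEvidence(FunctionalCall("v1", "functionally_abnormal"), weak, mechLof)
  a2 <- applyEvidence(FunctionalCall("v1", "functionally_normal"), strong, mechLof)
  a3 <- applyEvidence(FunctionalCall("v1", "indeterminate"), weak, mechLof)
  apps <- list(a1, a2, a3)
  ref <- combineEvidence(apps, instances)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    out <- combineEvidence(apps[perm], instances)
    expect_identical(tierLabel(out), tierLabel(ref))
    expect_identical(out@instanceId, ref@instanceId)
  }
  expect_identical(tierLabel(combineEvidence(list(a1), instances)),
                   tierLabel(a1))
  expect_error(combineEvidence(list(a1, applyEvidence(
    FunctionalCall("v2", "functionally_normal"), weak, mechLof)), instances),
    "different variants")
})

test_that("the 50-nt NMD boundary rule follows coding coordinates", {
  expect_true(nmdSubject(120, c(100, 100, 100)))
  expect_false(nmdSubject(151, c(100, 100, 100)))
  expect_true(nmdSubject(150, c(100, 100, 100)))   # boundary itself triggers
  expect_false(nmdSubject(250, c(100, 100, 100)))  # last exon escapes
  expect_message(res <- nmdSubject(40, 300), "single-exon")
  expect_false(res)
  expect_match(attr(res, "note"), "inapplicable")
  expect_error(nmdSubject(500, c(100, 100)), "within the transcript")
  expect_error(nmdSubject(0, c(100, 100)), "coordinate")
})
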