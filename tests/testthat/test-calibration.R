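test_that("per-variant summarization is the median across instances", {
  expect_equal(summarizeVariantReadout(c(12, 15, 70)), 15)
  expect_equal(summarizeVariantReadout(75), 75)
  expect_equal(summarizeVariantReadout(c(40, 60)), 50)
  expect_error(summarizeVariantReadout(numeric()), "non-empty")
})

test_that("threshold selection reproduces the worked-example cutoffs", {
  fx <- exampleFixture()
  th <- selectThresholds(fx$controls)
  expect_equal(normalCutoff(th), 60)
  expect_equal(abnormalCutoff(th), 30)
  expect_identical(polarity(th), "higher_is_normal")
  expect_identical(attr(th, "demoted"), "B6")
})

test_that("cutoffs snap to the grid against the class extremes", {
  ctl <- makeControls(benign = c(80, 85, 92), pathogenic = c(2, 6, 10))
  th <- selectThresholds(ctl, gridStep = 5)
  expect_equal(normalCutoff(th), 80)
  expect_equal(abnormalCutoff(th), 10)
  expect_length(attr(th, "demoted"), 0)
})

test_that("inseparable controls produce an error suggesting manual override", {
  ctl <- makeControls(benign = 50, pathogenic = 55)
  expect_error(selectThresholds(ctl, polarity = "higher_is_normal"),
               "inseparable")
})

test_that("lower_is_normal assays mirror the selection", {
  ctl <- makeControls(benign = c(5, 10, 15), pathogenic = c(70, 80, 90))
  th <- selectThresholds(ctl)
  expect_identical(polarity(th), "lower_is_normal")
  expect_equal(normalCutoff(th), 15)
  expect_equal(abnormalCutoff(th), 70)
  expect_identical(classifyReadout(c(8, 40, 95), th),
                   c("functionally_normal", "indeterminate",
                     "functionally_abnormal"))
})

test_that("classifyReadout is monotone with inclusive cutoffs", {
  th <- new("ReadoutThresholds", normalCutoff = 60, abnormalCutoff = 30,
            polarity = "higher_is_normal")
  expect_identical(classifyReadout(c(75, 45, 12), th),
                   c("functionally_normal", "indeterminate",
                     "functionally_abnormal"))
  expect_identical(classifyReadout(60, th), "functionally_normal")
  expect_identical(classifyReadout(30, th), "functionally_abnormal")
  vals <- seq(0, 100, by = 0.5)
  zones <- classifyReadout(vals, th)
  rank <- c(functionally_abnormal = 1, indeterminate = 2,
            functionally_normal = 3)[zones]
  expect_true(all(diff(rank) >= 0))
})

test_that("calibration composes counts, thresholds and OddsPath", {
  cal <- calibrate(exampleFixture()$controls)
  expect_equal(unname(controlCounts(cal)), c(5L, 5L, 1L, 0L))
  expect_equal(oddsPathPathogenic(oddsPath(cal)), 5.0)
  expect_equal(oddsPathBenign(oddsPath(cal)), 0.2)
  expect_identical(tierLabel(mapStrength(oddsPathPathogenic(oddsPath(cal)))),
                   "PS3_moderate")
})

test_that("fully concordant controls give the closed-form OddsPath", {
  cal <- calibrate(makeControls(benign = c(70, 80, 90),
                                pathogenic = c(5, 10, 15)))
  expect_equal(oddsPathPathogenic(oddsPath(cal)), 3.0)
  expect_equal(oddsPathBenign(oddsPath(cal)), 1 / 3)
  expect_equal(sum(controlCounts(cal)[c("indeterminate", "discordant")]), 0L)
})

test_that("controls classified with functional evidence are rejected", {
  ctl <- makeControls(benign = c(70, 80), pathogenic = c(5, 10))
  ctl$classification_basis[1] <- "PS3;PM2"
  expect_error(calibrate(ctl), "circularity")
  ctl$classification_basis[1] <- "BS3_supporting"
  expect_error(calibrate(ctl), "circularity")
})

test_that("calibration is invariant to row order and readout duplication", {
  fx <- exampleFixture()
  base <- calibrate(fx$controls)
  shuffled <- calibrate(fx$controls[rev(seq_len(nrow(fx$controls))), ])
  expect_equal(controlCounts(shuffled), controlCounts(base))
  expect_equal(normalCutoff(thresholds(shuffled)), normalCutoff(thresholds(base)))
  expect_equal(oddsPathPathogenic(oddsPath(shuffled)),
               oddsPathPathogenic(oddsPath(base)))
  # duplicating every instance readout leaves the medians unchanged
  doubled <- fx$controls
  doubled$assay_instance_id <- paste0(doubled$assay_instance_id, "_dup")
  both <- rbind(fx$controls, doubled)
  cal2 <- calibrate(both)
  expect_equal(controlCounts(cal2), controlCounts(base))
  expect_equal(abnormalCutoff(thresholds(cal2)), abnormalCutoff(thresholds(base)))
})

test_that("a side without concordant controls yields a summary without OddsPath", {
  ctl <- makeControls(benign = 50, pathogenic = c(5, 10, 15))
  th <- new("ReadoutThresholds", normalCutoff = 60, abnormalCutoff = 30,
            polarity = "higher_is_normal")
  expect_warning(cal <- calibrate(ctl, thresholds = th), "zero concordant")
  expect_null(oddsPath(cal))
  expect_equal(unname(controlCounts(cal)["indeterminate"]), 1L)
})

test_that("user-supplied thresholds can expose discordant controls", {
  ctl <- makeControls(benign = c(25, 70, 80), pathogenic = c(5, 10))
  th <- new("ReadoutThresholds", normalCutoff = 60, abnormalCutoff = 30,
            polarity = "higher_is_normal")
  cal <- calibrate(ctl, thresholds = th)
  expect_equal(unname(controlCounts(cal)["discordant"]), 1L)
  # the discordant benign control is excluded from the adjusted contingency
  expect_equal(oddsPathPathogenic(oddsPath(cal)), 2.0)
})

test_that("default selection never yields discordant controls", {
  for (seed in 1:25) {
    nB <- 2 + seed %% 5; nP <- 2 + (seed * 3) %% 5
    cal <- calibrate(randomControlSet(nB, nP, seed = seed))
    expect_equal(unname(controlCounts(cal)["discordant"]), 0L)
  }
})
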