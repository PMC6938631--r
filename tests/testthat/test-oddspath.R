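test_that("computeOddsPath evaluates the likelihood-ratio formula", {
  expect_equal(computeOddsPath(0.5, 0.5), 1.0)
  expect_equal(computeOddsPath(0.5, 5 / 6), 5.0)
  expect_equal(computeOddsPath(0.5, 1 / 6), 0.2)
  # independent arithmetic: (p2 (1-p1)) / ((1-p2) p1) at a non-symmetric prior
  expect_equal(computeOddsPath(0.2, 0.7), (0.7 * 0.8) / (0.3 * 0.2))
})

test_that("boundary probabilities are rejected with a pointer to the adjustment", {
  for (bad in list(c(0, 0.5), c(1, 0.5), c(0.5, 0), c(0.5, 1), c(-0.1, 0.5)))
    expect_error(computeOddsPath(bad[1], bad[2]), "adjust")
})

test_that("posterior equal to prior gives odds of exactly 1 across a grid", {
  for (p in seq(0.02, 0.98, by = 0.02))
    expect_equal(computeOddsPath(p, p), 1.0, tolerance = 1e-12)
})

test_that("OddsPath is monotone in the posterior and antitone in the prior", {
  p2 <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(p2, function(x) computeOddsPath(0.3, x), numeric(1))
  expect_true(all(diff(vals) > 0))
  p1 <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(p1, function(x) computeOddsPath(x, 0.3), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("adjustedContingency adds exactly one misclassified variant per set", {
  ct <- adjustedContingency(5, 5, 1)
  expect_s4_class(ct, "AdjustedContingency")
  expect_identical(ct@nBenignConcordant, 5L)
  expect_identical(ct@nPathogenicConcordant, 5L)
  expect_identical(ct@nIndeterminate, 1L)
  minimal <- adjustedContingency(1, 1)
  expect_identical(minimal@nIndeterminate, 0L)
  expect_error(adjustedContingency(0, 5), "benign")
  expect_error(adjustedContingency(5, 0), "pathogenic")
})

test_that("oddsPathFromControls matches the closed forms B and 1/P", {
  res <- oddsPathFromControls(adjustedContingency(5, 5, 1))
  expect_equal(oddsPathPathogenic(res), 5.0)
  expect_equal(oddsPathBenign(res), 0.2)
  expect_equal(priorP1(res), 0.5)
  # exhaustive check against the formula pipeline
  for (B in 1:20) for (P in 1:20) {
    r <- oddsPathFromControls(adjustedContingency(B, P))
    expect_equal(oddsPathPathogenic(r), B, tolerance = 1e-12)
    expect_equal(oddsPathBenign(r), 1 / P, tolerance = 1e-12)
  }
  # one of each: both posteriors collapse onto the prior
  r <- oddsPathFromControls(adjustedContingency(1, 1))
  expect_equal(oddsPathPathogenic(r), 1.0)
  expect_equal(oddsPathBenign(r), 1.0)
})

test_that("mapStrength reproduces the strength-equivalence table", {
  expect_identical(tierLabel(mapStrength(5.0, "pathogenic")), "PS3_moderate")
  expect_identical(tierLabel(mapStrength(1.0, "pathogenic")), "none")
  expect_identical(tierLabel(mapStrength(0.2, "benign")), "BS3_moderate")
  expect_identical(tierLabel(mapStrength(400, "pathogenic")), "PS3_very_strong")
  expect_identical(tierLabel(mapStrength(20, "pathogenic")), "PS3")
  expect_identical(tierLabel(mapStrength(3, "pathogenic")), "PS3_supporting")
  expect_identical(tierLabel(mapStrength(0.3, "benign")), "BS3_supporting")
  expect_identical(tierLabel(mapStrength(0.04, "benign")), "BS3")
  expect_error(mapStrength(0), "positive")
  expect_error(mapStrength(-2), "positive")
})

test_that("the code follows the value, not the query direction", {
  low <- mapStrength(0.2, "pathogenic")
  expect_identical(low@code, "BS3")
  high <- mapStrength(5, "benign")
  expect_identical(high@code, "PS3")
})

test_that("mapStrength is a non-decreasing step function of OddsPath", {
  grid <- sort(c(10^seq(-3, 3, length.out = 200), 0.053, 0.23, 0.48, 2.1,
                 4.3, 18.7, 350))
  signedRank <- vapply(grid, function(x) {
    st <- mapStrength(x)
    tierRank(st@tier) * ifelse(st@code == "BS3", -1L, 1L)
  }, numeric(1))
  expect_true(all(diff(signedRank) >= 0))
})

test_that("an OddsPath on a boundary falls in the weaker tier", {
  expect_identical(tierLabel(mapStrength(2.1)), "none")
  expect_identical(tierLabel(mapStrength(4.3)), "PS3_supporting")
  expect_identical(tierLabel(mapStrength(0.48)), "none")
  expect_identical(tierLabel(mapStrength(0.23)), "BS3_supporting")
})

test_that("the one-indeterminate grid reproduces known splits", {
  grid <- minimumControlsGrid(10, "one_indeterminate")
  row <- grid[grid$n_benign == 4 & grid$n_pathogenic == 4, ]
  expect_identical(row$indeterminate_side, "benign")  # tie goes to benign
  expect_equal(row$oddspath_pathogenic, 3.0)
  expect_equal(row$oddspath_benign, 0.25)
  expect_identical(row$tier_pathogenic, "PS3_supporting")
  expect_identical(row$tier_benign, "BS3_supporting")
  # worst-case placement columns are present and never stronger than default
  expect_true(all(c("oddspath_pathogenic_worst", "tier_benign_worst") %in%
                    names(grid)))
  ok <- !is.na(grid$oddspath_pathogenic_worst)
  expect_true(all(grid$oddspath_pathogenic_worst[ok] <=
                    grid$oddspath_pathogenic[ok]))
})

test_that("a perfect single pair of controls is indeterminate evidence", {
  grid <- minimumControlsGrid(2, "perfect")
  row <- grid[grid$n_benign == 1 & grid$n_pathogenic == 1, ]
  expect_equal(row$oddspath_pathogenic, 1.0)
  expect_equal(row$oddspath_benign, 1.0)
  expect_identical(row$tier_pathogenic, "none")
  expect_identical(row$tier_benign, "none")
})

test_that("minimum total for moderate evidence in both directions is 11", {
  res <- minimumControlsForModerate(20, "one_indeterminate")
  expect_identical(res$minimumTotal, 11L)
  below <- res$table[res$table$n_total <= 10, ]
  expect_true(all(!below$both_at_least_moderate))
})
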