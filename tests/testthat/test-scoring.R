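test_that("tier fractions land on the quartile lattice", {
  expect_equal(tier_fraction(0, 0, 1), 0)          # strain at the negative control
  expect_equal(tier_fraction(0.3, 0, 1), 0.5)
  expect_equal(tier_fraction(0.6, 0, 1), 0.75)
  expect_equal(tier_fraction(0.9, 0, 1), 1)
  # indistinguishable from the positive control scores full marks
  expect_equal(tier_fraction(0.4, 0, 1, sig_below_positive = FALSE), 1)
  # small but significant exceedance of the negative earns a quarter
  expect_equal(tier_fraction(0.1, 0, 1, sig_above_negative = TRUE,
                             sig_below_positive = TRUE), 0.25)
  expect_equal(tier_fraction(0.1, 0, 1, sig_above_negative = FALSE,
                             sig_below_positive = TRUE), 0)
  # the published IBA titers: 0.5 of a 0.88 reference -> 2.25 of 3 points
  expect_equal(3 * tier_fraction(0.5, 0, 0.88, sig_above_negative = TRUE,
                                 sig_below_positive = TRUE), 2.25)
  expect_error(tier_fraction(1, 2, 1), "invalid reference")
})

test_that("probit scores follow the cumulative normal", {
  expect_equal(probit_score(5, 5, 2, 8), 4)                 # Phi(0) = 1/2
  expect_equal(probit_score(3, 0, 1, 7), 6.9906, tolerance = 1e-4)
  expect_equal(probit_score(1.0364, 0, 1, 7), 5.95, tolerance = 0.01)
  x <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(probit_score(x, 0, 1, 7)) > 0))
  expect_error(probit_score(1, 0, 0, 7), "positive")
})

test_that("binary outcomes score all-or-nothing with missing kept distinct", {
  expect_equal(score_binary("positive", 4), 4)
  expect_equal(score_binary("negative", 4), 0)
  expect_true(is.na(score_binary("missing", 4)))
  expect_error(score_binary("maybe", 4), "outcome")
})

test_that("fungal inhibition is the day-wise complement of relative growth", {
  same <- fungal_inhibition(c(4, 6, 8), c(4, 6, 8))
  expect_equal(same$per_day, c(0, 0, 0))
  full <- fungal_inhibition(c(0, 0, 0), c(4, 6, 8))
  expect_equal(full$mean, 1)
  half <- fungal_inhibition(c(2, 3, 4), c(4, 6, 8))
  expect_equal(half$mean, 0.5)
  expect_error(fungal_inhibition(c(1, 2), c(4, 6, 8)), "same days")
  expect_error(fungal_inhibition(c(1, 2, 3), c(4, 0, 8)), "positive")
})

test_that("a panel of control-level strains earns zero tiered subscores", {
  prof <- setNames(rep(0, 18), apsi_battery()$test_id)
  sub <- build_subscore_table(profile_panel(prof, noise_cv = 0))
  tiered <- sub[sub$test_id %in%
                  apsi_battery()$test_id[apsi_battery()$scheme == "tiered"], ]
  expect_true(all(tiered$points == 0))
  # binary rows come from outcomes, not tiers-as-points
  expect_equal(sub$points[sub$test_id == "siderophore"], 0)
})

test_that("binary subscore rows reproduce the published qualitative pattern", {
  fx <- table3_fixture()
  sid <- fx$scores[fx$scores$test_id == "siderophore", ]
  expect_equal(sid$points, rep(4, 4))
  pot <- fx$scores[fx$scores$test_id == "potassium_solubilization", ]
  expect_equal(pot$points, rep(4, 4))
  ure <- fx$scores[fx$scores$test_id == "urea_hydrolysis", ]
  expect_equal(ure$points[!ure$missing], rep(0, 3))
  expect_identical(ure$strain[ure$missing], "FZB42")
})

test_that("a tiered test without its positive control is a configuration error", {
  prof <- setNames(rep(0.5, 18), apsi_battery()$test_id)
  panel <- profile_panel(prof, noise_cv = 0)
  panel$controls <- panel$controls[names(panel$controls) != "positive_control"]
  expect_error(build_subscore_table(panel), "positive_control")
})

test_that("subscores stay within their per-test maxima and sum to the index scale", {
  b <- apsi_battery()
  expect_equal(sum(b$max_score), 100)
  prof <- table3_profile("FZB42")
  sub <- build_subscore_table(profile_panel(prof, noise_cv = 0.05, seed = 2))
  ok <- sub$missing | (sub$points >= 0 & sub$points <= sub$max_score)
  expect_true(all(ok))
  expect_error(subscore_table(data.frame(strain = "A", test_id = "rwc_pgpr",
                                         points = 99), b), "outside")
})

test_that("tier and probit schemes agree at the effect extremes", {
  # far below the references -> (near) zero; far above -> (near) max
  expect_equal(tier_fraction(0, 0, 1) * 7, 0)
  expect_equal(tier_fraction(1, 0, 1) * 7, 7)
  expect_lt(probit_score(0, 0.5, 1 / 3, 7), 0.5)
  expect_gt(probit_score(1, 0.5, 1 / 3, 7), 6.5)
})
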