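test_that("weight schemes must be non-negative and sum to 100", {
  expect_s3_class(default_weights(), "weight_scheme")
  expect_equal(sum(default_weights()), 100)
  expect_error(weight_scheme(c(a = 50, b = 49)), "sum to 100")
  expect_error(weight_scheme(c(a = 110, b = -10)), "non-negative")
  expect_error(weight_scheme(c(50, 50)), "named")
})

test_that("budget allocation reproduces the published per-test maxima", {
  counts <- c(growth = 4, drought = 3, fungal = 4, hormone = 3,
              solubilization = 2, siderophore = 1, urease = 1)
  per_test <- allocate_budgets(default_weights(), counts)
  expect_equal(per_test[names(counts)],
               c(growth = 5, drought = 9, fungal = 7, hormone = 3,
                 solubilization = 4, siderophore = 4, urease = 4))
  # mass preservation: counts x maxima returns the full 100 points
  expect_equal(sum(per_test[names(counts)] * counts), 100)
  expect_equal(unname(allocate_budgets(weight_scheme(c(x = 100)), c(x = 1))), 100)
  expect_equal(unname(allocate_budgets(weight_scheme(c(a = 50, b = 50)),
                                       c(a = 2, b = 5))), c(25, 10))
  expect_error(allocate_budgets(weight_scheme(c(a = 50, b = 50)), c(a = 2)),
               "no tests")
})

test_that("one Delphi round takes medians and contracts experts", {
  e <- rbind(c(20, 80), c(40, 60))
  colnames(e) <- c("growth", "drought")
  st <- delphi_round(delphi_state(e), contraction = 0)
  expect_equal(unname(st$aggregate), c(30, 70))
  expect_equal(st$experts, e)       # contraction 0 leaves opinions unchanged
  expect_equal(st$round, 1L)
  same <- delphi_state(rbind(c(25, 75), c(25, 75)))
  st2 <- delphi_round(same, contraction = 0.7)
  expect_equal(st2$experts, same$experts)   # consensus is a fixed point
  expect_equal(max(st2$dispersion), 0)
  expect_error(delphi_round(delphi_state(matrix(100, 1, 1)), 0.5), "2 experts")
})

test_that("Delphi dispersion never grows under contraction", {
  for (s in 1:10) {
    st <- generate_expert_panel(7, default_weights(), disagreement_sd = 8,
                                seed = s)
    prev <- max(st$dispersion)
    for (r in 1:6) {
      st <- delphi_round(st, contraction = runif(1, 0.1, 0.9))
      expect_lte(max(st$dispersion), prev + 1e-9)
      prev <- max(st$dispersion)
    }
  }
})

test_that("Delphi convergence returns a normalized scheme with round count", {
  same <- delphi_state(rbind(c(25, 75), c(25, 75), c(25, 75)))
  out <- delphi_converge(same, tolerance = 0.1)
  expect_equal(attr(out, "rounds"), 1L)
  expect_true(attr(out, "converged"))
  expect_equal(unname(as.numeric(out)), c(25, 75))

  st <- generate_expert_panel(9, default_weights(), disagreement_sd = 5, seed = 2)
  sch <- delphi_converge(st, tolerance = 0.1, contraction = 0.5)
  expect_true(attr(sch, "converged"))
  expect_equal(sum(sch), 100)

  stuck <- delphi_state(rbind(c(20, 80), c(40, 60)))
  expect_warning(out <- delphi_converge(stuck, tolerance = 0.1, max_rounds = 5,
                                        contraction = 0),
                 "did not reach consensus")
  expect_false(attr(out, "converged"))
})

test_that("the aggregate is permutation-invariant over experts", {
  st <- generate_expert_panel(6, default_weights(), disagreement_sd = 6, seed = 3)
  perm <- delphi_state(st$experts[c(4, 1, 6, 2, 5, 3), ])
  expect_equal(st$aggregate, perm$aggregate)
  expect_equal(st$dispersion, perm$dispersion)
})

test_that("synthetic expert panels are reproducible and well-formed", {
  a <- generate_expert_panel(5, disagreement_sd = 5, seed = 11)
  b <- generate_expert_panel(5, disagreement_sd = 5, seed = 11)
  expect_identical(a, b)
  expect_true(all(abs(rowSums(a$experts) - 100) < 1e-9))
  flat <- generate_expert_panel(4, disagreement_sd = 0, seed = 1)
  expect_true(all(abs(t(flat$experts) - as.numeric(default_weights())) < 1e-9))
  # consensus recovers the shared prior on average: the median of nine
  # sd-5 opinions scatters about 2 points, so the calibration is on the
  # mean absolute deviation across categories and panels
  devs <- unlist(lapply(1:10, function(s) {
    sch <- delphi_converge(generate_expert_panel(9, disagreement_sd = 5,
                                                 seed = s), tolerance = 0.1)
    abs(as.numeric(sch) - as.numeric(default_weights()))
  }))
  expect_lt(mean(devs), 2)
})
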