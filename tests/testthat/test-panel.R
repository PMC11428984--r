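test_that("relative water content follows the fresh/dry/turgid formula", {
  expect_equal(compute_rwc(3, 1, 3), 1.0)   # fully turgid
  expect_equal(compute_rwc(1, 1, 3), 0.0)   # fully dry
  expect_equal(compute_rwc(2, 1, 3), 0.5)
  expect_error(compute_rwc(2, 3, 3), "degenerate")
  expect_error(compute_rwc(4, 1, 3), "clip")
  expect_warning(out <- compute_rwc(4, 1, 3, clip = TRUE), "clamped")
  expect_equal(out, 1.0)
})

test_that("RWC is bounded and strictly increasing in fresh weight", {
  set.seed(42)
  for (i in 1:200) {
    dw <- runif(1, 0.1, 2)
    tw <- dw + runif(1, 0.5, 5)
    fw <- runif(2, dw, tw)
    r <- compute_rwc(sort(fw), dw, tw)
    expect_true(all(r >= 0 & r <= 1))
    if (diff(fw) != 0) expect_true(diff(r) > 0)
  }
})

test_that("panel validation enforces enums, signs and key uniqueness", {
  expect_error(assay_panel("A", plant = data.frame(
    strain = "A", condition = "flooded", day = 31, replicate = 1,
    fresh_weight = 2, dry_weight = 1, turgid_weight = 3,
    root_length = 10, stem_length = 15)), "condition")
  expect_error(assay_panel("A", plant = data.frame(
    strain = "A", condition = "irrigated", day = 31, replicate = 1,
    fresh_weight = -2, dry_weight = 1, turgid_weight = 3,
    root_length = 10, stem_length = 15)), "negative")
  expect_error(assay_panel("A", binary = data.frame(
    strain = "B", assay = "siderophore", outcome = "positive")), "not in panel")
  dup <- data.frame(strain = "A", assay = "siderophore",
                    outcome = c("positive", "negative"))
  expect_error(assay_panel("A", binary = dup), "duplicate")
  # missing is a state of its own, not a negative
  p <- assay_panel("A", binary = data.frame(strain = "A", assay = "urease",
                                            outcome = "missing"))
  expect_identical(p$binary$outcome, "missing")
})

test_that("long-format CSV loading is strict and keeps row provenance", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- "strain,assay,condition,fungus,mode,hormone,day,time_h,replicate,value,unit"
  writeLines(hdr, f)
  p <- load_panel(f, config = list(strains = c("A", "B"), controls = character()))
  expect_s3_class(p, "assay_panel")
  expect_identical(p$strains, c("A", "B"))
  expect_equal(nrow(p$plant) + nrow(p$halo) + nrow(p$binary), 0)

  # published DSM7 phosphate halo value survives ingestion
  writeLines(c(hdr, "DSM7,phosphate,,,,,,,1,3.3,cm"), f)
  p <- load_panel(f)
  expect_equal(p$halo$halo_diameter, 3.3)
  expect_identical(p$halo$strain, "DSM7")

  writeLines(c(hdr,
               "A,dry_weight,flooded,,,,31,,1,1.0,g"), f)
  expect_error(load_panel(f), "condition.*line.*2")
  writeLines(c(hdr, "A,plate_count,,,,,,,1,5,cm"), f)
  expect_error(load_panel(f), "unknown assay")
  writeLines(c(hdr, "A,phosphate,,,,,,,1,-2,cm"), f)
  expect_error(load_panel(f), "negative")
  writeLines(c(hdr, "A,phosphate,,,,,,,1,2,mm"), f)
  expect_error(load_panel(f), "unit")
})

test_that("write_panel / load_panel round-trips a generated panel", {
  prof <- table3_profile("D747")
  panel <- profile_panel(prof, replicates = 3, noise_cv = 0.05, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- load_panel(f, config = list(strains = panel$strains,
                                      controls = panel$controls))
  for (part in c("plant", "fungal", "halo", "hormone", "binary")) {
    a <- panel[[part]]
    b <- back[[part]][names(a)]
    key_cols <- names(a)[!vapply(a, is.numeric, logical(1))]
    ord <- function(d) do.call(order, d[c(key_cols, setdiff(names(d), key_cols))])
    expect_equal(a[ord(a), ], b[ord(b), ], ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("trait flags are all-false when strains equal the control", {
  lv <- list(irrigated = base_plant_level(), drought = base_plant_level(0.6, 8, 12, 0.3))
  levels <- list(A = lv, B = lv, ctrl = lv, pos = lv)
  panel <- plant_only_panel(levels, seed = 3)
  tr <- classify_strain_traits(panel, method = "raw")
  # identical generating distributions: significance mode must find nothing
  tr_sig <- classify_strain_traits(panel)
  expect_false(any(tr_sig$is_pgpr))
  expect_false(any(tr_sig$is_drought_protectant))
})

test_that("a +50% root/stem strain under irrigation is PGPR but not drought protectant", {
  ctrl_lv <- list(irrigated = base_plant_level(), drought = base_plant_level(0.6, 8, 12, 0.3))
  big <- ctrl_lv
  big$irrigated[c("rl", "sl")] <- 1.5 * big$irrigated[c("rl", "sl")]
  levels <- list(A = big, ctrl = ctrl_lv, pos = ctrl_lv)
  panel <- plant_only_panel(levels, seed = 11)
  tr <- classify_strain_traits(panel)
  expect_true(tr$is_pgpr[tr$strain == "A"])
  expect_false(tr$is_drought_protectant[tr$strain == "A"])
  # oracle: direct group-mean comparison on the same replicates
  p <- panel$plant[panel$plant$condition == "irrigated", ]
  comb <- p$root_length + p$stem_length
  expect_gt(mean(comb[p$strain == "A"]), mean(comb[p$strain == "ctrl"]))
})

test_that("drought dry weight and RWC shifted +3 SD flag drought protection", {
  sd_frac <- 0.04
  ctrl_lv <- list(irrigated = base_plant_level(), drought = base_plant_level(0.6, 8, 12, 0.3))
  shifted <- ctrl_lv
  shifted$drought[["dw"]] <- 0.6 * (1 + 3 * sd_frac)
  shifted$drought[["rwc"]] <- 0.3 * (1 + 3 * sd_frac)
  levels <- list(A = shifted, ctrl = ctrl_lv, pos = ctrl_lv)
  panel <- plant_only_panel(levels, replicates = 8, sd_frac = sd_frac, seed = 5)
  tr <- classify_strain_traits(panel)
  expect_true(tr$is_drought_protectant[tr$strain == "A"])
  # oracle: Welch comparison on the generated drought replicates
  p <- panel$plant[panel$plant$condition == "drought", ]
  for (m in list(p$dry_weight,
                 compute_rwc(p$fresh_weight, p$dry_weight, p$turgid_weight))) {
    w <- t.test(m[p$strain == "A"], m[p$strain == "ctrl"],
                alternative = "greater")
    expect_lt(w$p.value, 0.05)
  }
})

test_that("a missing plant control is a configuration error", {
  lv <- list(irrigated = base_plant_level(), drought = base_plant_level())
  panel <- plant_only_panel(list(A = lv, pos = lv),
                            controls = c(positive_control = "pos"))
  expect_error(classify_strain_traits(panel), "plant_control")
})
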