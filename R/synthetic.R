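#' Reference levels for the synthetic panel generator
#'
#' Negative (uninoculated / non-producing control) and positive (reference
#' PGPR) mean levels per assay family, on the package's fixed units. The
#' defaults emulate the magnitudes typical of pot-scale pepper trials and
#' plate assays: gram-scale plant biometry with a several-fold water
#' capacity, fungal colonies growing from 4 to 8 cm over the three sampling
#' days, centimeter-scale solubilization halos, and hormone titers spanning
#' the published control values (e.g. a reference IAA titer of 212 ug/L).
#'
#' @return nested list with components `plant` (per condition: `dry_weight`,
#'   `root_length`, `stem_length`, `rwc` as `c(neg, pos)`, plus
#'   `water_capacity` in grams), `fungal` (control colony diameters named
#'   by day), `halo` (`phosphate = c(neg, pos)` in cm) and `hormone`
#'   (`c(neg, pos)` in ug/L per hormone).
#' @export
default_control_levels <- function() {
  list(
    plant = list(
      irrigated = list(dry_weight = c(neg = 1.2, pos = 1.8),
                       root_length = c(neg = 10, pos = 15),
                       stem_length = c(neg = 15, pos = 20),
                       rwc = c(neg = 0.80, pos = 0.95),
                       water_capacity = 6),
      drought = list(dry_weight = c(neg = 0.8, pos = 1.3),
                     root_length = c(neg = 8, pos = 12),
                     stem_length = c(neg = 12, pos = 14),
                     rwc = c(neg = 0.35, pos = 0.80),
                     water_capacity = 4)
    ),
    fungal = c("5" = 4, "10" = 6, "15" = 8),
    halo = list(phosphate = c(neg = 0.2, pos = 3.0)),
    hormone = list(IAA = c(neg = 5, pos = 212),
                   IBA = c(neg = 0.05, pos = 0.88),
                   GA3 = c(neg = 0, pos = 0.87))
  )
}

#' Configuration for the synthetic panel generator
#'
#' Describes the ground truth of a simulated strain panel: one effect-tier
#' profile per strain and test (a fraction in `[0, 1]`; `NA` marks a
#' qualitative outcome to be left missing), the replicate count per group,
#' the measurement noise as a coefficient of variation, and the control
#' reference levels.
#'
#' @param strains character vector of strain names.
#' @param tiers numeric matrix or data frame, rows = strains, columns =
#'   battery test ids, entries in `[0, 1]` or `NA`. Missing columns default
#'   to tier 0.
#' @param replicates replicates per (strain, condition) plant group and per
#'   halo group (>= 1).
#' @param noise_cv coefficient of variation of the measurement noise
#'   (>= 0; 0 gives a deterministic panel).
#' @param control_levels see [default_control_levels()]; positive reference
#'   means must exceed negative ones.
#' @param days fungal sampling days.
#' @param seed integer RNG seed.
#' @param battery the battery whose tests the tiers address.
#' @return object of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(strains, tiers, replicates = 6,
                                   noise_cv = 0.05,
                                   control_levels = default_control_levels(),
                                   days = c(5, 10, 15), seed = 1,
                                   battery = apsi_battery()) {
  tiers <- as.matrix(tiers)
  if (is.null(rownames(tiers))) rownames(tiers) <- strains
  full <- matrix(0, length(strains), nrow(battery),
                 dimnames = list(strains, battery$test_id))
  shared <- intersect(colnames(tiers), battery$test_id)
  full[, shared] <- tiers[strains, shared, drop = FALSE]
  if (any(!is.na(full) & (full < 0 | full > 1)))
    stop("tiers must lie in [0, 1]", call. = FALSE)
  if (replicates < 1) stop("need at least 1 replicate", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  for (cond in c("irrigated", "drought")) {
    lv <- control_levels$plant[[cond]]
    for (m in c("dry_weight", "root_length", "stem_length", "rwc"))
      if (lv[[m]][["pos"]] <= lv[[m]][["neg"]])
        stop("inconsistent control levels: plant ", cond, " ", m, call. = FALSE)
  }
  if (control_levels$halo$phosphate[["pos"]] <= control_levels$halo$phosphate[["neg"]])
    stop("inconsistent control levels: phosphate halo", call. = FALSE)
  for (h in names(control_levels$hormone))
    if (control_levels$hormone[[h]][["pos"]] <= control_levels$hormone[[h]][["neg"]])
      stop("inconsistent control levels: hormone ", h, call. = FALSE)
  structure(list(strains = as.character(strains), tiers = full,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 control_levels = control_levels, days = days,
                 seed = as.integer(seed), battery = battery),
            class = "synthetic_panel_config")
}

# Representative effect ratio for a target score fraction: lattice fractions
# map to the midpoint of their tier band (so the tier rule recovers them
# exactly at zero noise); off-lattice fractions pass through unchanged.
tier_to_ratio <- function(tier) {
  lattice <- c(0, 0.25, 0.5, 0.75, 1)
  mids <- c(0, 0.125, 0.375, 0.625, 1)
  vapply(tier, function(t) {
    if (is.na(t)) return(NA_real_)
    i <- which(abs(lattice - t) < 1e-9)
    if (length(i)) mids[i] else t
  }, numeric(1))
}

# Mean-preserving lognormal noise: E[x] = target, CV = cv.
lnoise <- function(n, target, cv) {
  if (cv == 0 || target == 0) return(rep(target, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(target) - sdlog^2 / 2, sdlog = sdlog)
}

# Truncated-normal noise for bounded quantities.
tnoise <- function(n, target, cv, lo = 0, hi = Inf) {
  if (cv == 0) return(rep(target, n))
  pmin(pmax(stats::rnorm(n, target, cv * max(target, 1e-12)), lo), hi)
}

#' Generate a synthetic assay panel
#'
#' Draws a full raw-measurement panel with the statistical structure the
#' scoring pipeline assumes: replicate groups with negative and positive
#' controls, monotone treatment effects set by each strain's tier profile,
#' and multiplicative measurement noise. Plant biometry is built from dry
#' weight and water fractions (lognormal dry weight and water capacity,
#' truncated-normal RWC) so that dry <= fresh <= turgid holds by
#' construction; fungal colony diameters shrink with the tier (inhibition
#' equals the tier's representative effect ratio); halo diameters and
#' hormone titers interpolate between the negative and positive control
#' levels; qualitative outcomes are positive exactly when the tier is
#' >= 0.5. Reproducible from the config seed. At zero noise a lattice tier
#' profile scores back to itself exactly (see `tier_to_ratio`).
#'
#' @param config a [synthetic_panel_config()].
#' @return an [assay_panel()] whose controls are `control_plant`,
#'   `control_positive`, `control_negative` and `control_fungal`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  set.seed(config$seed)
  cv <- config$noise_cv
  reps <- config$replicates
  lv <- config$control_levels
  tiers <- config$tiers
  strains <- config$strains

  ratio_of <- function(strain, test) {
    if (strain == "control_plant" || strain == "control_negative") return(0)
    if (strain == "control_positive") return(1)
    r <- tier_to_ratio(tiers[strain, test])
    if (is.na(r)) 0 else r
  }

  # plant biometry -------------------------------------------------------
  plant_ids <- c(strains, "control_plant", "control_positive")
  plant <- do.call(rbind, lapply(c("irrigated", "drought"), function(cond) {
    suffix <- if (cond == "irrigated") "pgpr" else "drought"
    pl <- lv$plant[[cond]]
    lerp <- function(metric, r) {
      v <- pl[[metric]]
      v[["neg"]] + r * (v[["pos"]] - v[["neg"]])
    }
    do.call(rbind, lapply(plant_ids, function(s) {
      dw <- lnoise(reps, lerp("dry_weight", ratio_of(s, paste0("dry_weight_", suffix))), cv)
      W <- lnoise(reps, pl$water_capacity, cv)
      rwc <- tnoise(reps, lerp("rwc", ratio_of(s, paste0("rwc_", suffix))), cv,
                    lo = 0.01, hi = 0.999)
      rl <- lnoise(reps, lerp("root_length", ratio_of(s, paste0("root_length_", suffix))), cv)
      sl_r <- if (cond == "irrigated") ratio_of(s, "stem_length_pgpr") else 0
      sl <- lnoise(reps, lerp("stem_length", sl_r), cv)
      data.frame(strain = s, condition = cond, day = 31,
                 replicate = seq_len(reps),
                 fresh_weight = dw + rwc * W, dry_weight = dw,
                 turgid_weight = dw + W, root_length = rl, stem_length = sl,
                 stringsAsFactors = FALSE)
    }))
  }))

  # fungal tracks ---------------------------------------------------------
  fungal_ids <- c(strains, "control_fungal")
  fungal <- do.call(rbind, lapply(c("F_oxysporum", "B_cinerea"), function(fg) {
    do.call(rbind, lapply(c("antagonism", "antibiosis"), function(md) {
      test <- paste0(md, "_", tolower(sub("F_oxysporum", "f_oxysporum",
                                          sub("B_cinerea", "b_cinerea", fg))))
      do.call(rbind, lapply(fungal_ids, function(s) {
        r <- if (s == "control_fungal") 0 else ratio_of(s, test)
        base <- lv$fungal[as.character(config$days)]
        d <- pmax(lnoise(length(base), 1, cv) * base * (1 - r), 0)
        data.frame(strain = s, fungus = fg, mode = md, day = config$days,
                   colony_diameter = d, stringsAsFactors = FALSE)
      }))
    }))
  }))

  # solubilization halos --------------------------------------------------
  halo_ids <- c(strains, "control_negative", "control_positive")
  hp <- lv$halo$phosphate
  halo <- do.call(rbind, lapply(halo_ids, function(s) {
    target <- hp[["neg"]] + ratio_of(s, "phosphate_solubilization") *
      (hp[["pos"]] - hp[["neg"]])
    data.frame(strain = s, assay = "phosphate", replicate = seq_len(reps),
               halo_diameter = tnoise(reps, target, cv, lo = 0),
               stringsAsFactors = FALSE)
  }))

  # hormone titers --------------------------------------------------------
  horm_ids <- c(strains, "control_negative", "control_positive")
  horm_tests <- c(IAA = "iaa_production", IBA = "iba_production",
                  GA3 = "ga3_production")
  hormone <- do.call(rbind, lapply(names(horm_tests), function(h) {
    hl <- lv$hormone[[h]]
    do.call(rbind, lapply(horm_ids, function(s) {
      target <- hl[["neg"]] + ratio_of(s, horm_tests[[h]]) *
        (hl[["pos"]] - hl[["neg"]])
      conc <- c(lnoise(1, target, cv),
                if (h == "GA3") 0 else lnoise(1, target, cv))
      data.frame(strain = s, hormone = h, time_h = c(24, 72),
                 concentration = conc, stringsAsFactors = FALSE)
    }))
  }))

  # qualitative outcomes --------------------------------------------------
  bin_tests <- c(siderophore = "siderophore",
                 potassium_qualitative = "potassium_solubilization",
                 urease = "urea_hydrolysis")
  binary <- do.call(rbind, lapply(names(bin_tests), function(a) {
    tier <- tiers[strains, bin_tests[[a]]]
    data.frame(strain = strains, assay = a,
               outcome = ifelse(is.na(tier), "missing",
                                ifelse(tier >= 0.5, "positive", "negative")),
               stringsAsFactors = FALSE)
  }))

  assay_panel(
    strains = strains,
    controls = c(plant_control = "control_plant",
                 positive_control = "control_positive",
                 negative_control = "control_negative",
                 fungal_control = "control_fungal"),
    plant = plant, fungal = fungal, halo = halo, hormone = hormone,
    binary = binary
  )
}

#' Generate a synthetic expert panel
#'
#' Expert weight vectors are the baseline scheme plus truncated normal
#' disagreement noise (clamped at zero), renormalized to sum to 100 -
#' a panel of imperfectly agreeing assessors around a shared prior.
#'
#' @param n_experts number of experts (>= 2).
#' @param baseline a [weight_scheme()].
#' @param disagreement_sd noise standard deviation, percentage points.
#' @param seed integer RNG seed.
#' @return a [delphi_state()] at round 0.
#' @export
generate_expert_panel <- function(n_experts, baseline = default_weights(),
                                  disagreement_sd = 5, seed = 1) {
  if (n_experts < 2) stop("need at least 2 experts", call. = FALSE)
  baseline <- weight_scheme(baseline)
  set.seed(seed)
  k <- length(baseline)
  m <- matrix(rep(as.numeric(baseline), each = n_experts), n_experts, k)
  if (disagreement_sd > 0)
    m <- pmax(m + matrix(stats::rnorm(n_experts * k, 0, disagreement_sd),
                         n_experts, k), 0)
  m <- m / rowSums(m) * 100
  colnames(m) <- names(baseline)
  delphi_state(m)
}
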