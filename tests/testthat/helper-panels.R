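# Shared fixture builders: everything is generated in code at test time.

# Panel engineered to a given tier profile (named by battery test ids).
profile_panel <- function(profile, replicates = 6, noise_cv = 0.05, seed = 1) {
  generate_panel(synthetic_panel_config(
    "S1", matrix(profile, nrow = 1, dimnames = list("S1", names(profile))),
    replicates = replicates, noise_cv = noise_cv, seed = seed))
}

# Hand-built plant biometry panel: per-strain means for the five metrics,
# gaussian replicate noise, both conditions. `levels` is a named list
# strain -> list(irrigated = c(dw, rl, sl, rwc), drought = c(dw, rl, sl, rwc)).
plant_only_panel <- function(levels, replicates = 6, sd_frac = 0.04, seed = 1,
                             controls = c(plant_control = "ctrl",
                                          positive_control = "pos")) {
  set.seed(seed)
  rows <- list()
  for (s in names(levels)) for (cond in c("irrigated", "drought")) {
    lv <- levels[[s]][[cond]]
    dw <- pmax(rnorm(replicates, lv[["dw"]], sd_frac * lv[["dw"]]), 0.01)
    W <- pmax(rnorm(replicates, 5, sd_frac * 5), 0.1)
    rwc <- pmin(pmax(rnorm(replicates, lv[["rwc"]], sd_frac * lv[["rwc"]]), 0.02), 0.99)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, condition = cond, day = 31, replicate = seq_len(replicates),
      fresh_weight = dw + rwc * W, dry_weight = dw, turgid_weight = dw + W,
      root_length = pmax(rnorm(replicates, lv[["rl"]], sd_frac * lv[["rl"]]), 0.1),
      stem_length = pmax(rnorm(replicates, lv[["sl"]], sd_frac * lv[["sl"]]), 0.1),
      stringsAsFactors = FALSE)
  }
  assay_panel(strains = setdiff(names(levels), unname(controls)),
              controls = controls, plant = do.call(rbind, rows))
}

base_plant_level <- function(dw = 1, rl = 10, sl = 15, rwc = 0.5)
  c(dw = dw, rl = rl, sl = sl, rwc = rwc)

# Random valid symmetric p-value matrix with unit diagonal.
random_p_matrix <- function(k, rng) {
  p <- matrix(1, k, k)
  up <- upper.tri(p)
  p[up] <- rng(sum(up))
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(p) <- list(paste0("g", 1:k), paste0("g", 1:k))
  p
}
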