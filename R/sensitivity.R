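# Dirichlet draws by the gamma-ratio construction.
rdirichlet_gamma <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  sw <- rowSums(x)
  sw[sw == 0] <- 1
  x / sw
}

new_sensitivity_report <- function(kind, n_draws, totals_draws, baseline_ranked,
                                   cutoff, band, seed, extra = list()) {
  strains <- colnames(totals_draws)
  base_rank <- stats::setNames(baseline_ranked$rank, baseline_ranked$strain)[strains]
  ranks <- do.call(rbind, lapply(seq_len(nrow(totals_draws)), function(i) {
    r <- rank_strains(data.frame(strain = strains, total = totals_draws[i, ],
                                 stringsAsFactors = FALSE))
    stats::setNames(r$rank, r$strain)[strains]
  }))
  report <- list(
    kind = kind, n_draws = n_draws, seed = seed,
    baseline = baseline_ranked,
    rank_stability = colMeans(ranks == matrix(base_rank, nrow(ranks),
                                              length(strains), byrow = TRUE)),
    total_intervals = t(apply(totals_draws, 2, stats::quantile,
                              probs = c(0.025, 0.975), names = TRUE)),
    crossing_probability = colMeans(totals_draws < cutoff - band),
    cutoff = cutoff, band = band
  )
  structure(c(report, extra), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%s, %d draws, seed %s):\n",
              x$kind, x$n_draws, format(x$seed)))
  tab <- data.frame(strain = names(x$rank_stability),
                    baseline_total = round(stats::setNames(
                      x$baseline$total, x$baseline$strain)[names(x$rank_stability)], 3),
                    rank_stability = round(x$rank_stability, 3),
                    lo_2.5 = round(x$total_intervals[, 1], 2),
                    hi_97.5 = round(x$total_intervals[, 2], 2),
                    p_below_cutoff = round(x$crossing_probability, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Weight-perturbation sensitivity of totals and ranks
#'
#' Draws category weight vectors from a Dirichlet distribution centred on
#' the working scheme (mean preserved; spread governed by `concentration` -
#' the Dirichlet concentration parameter, with larger values giving draws
#' closer to the baseline), reallocates per-test budgets for each draw,
#' rescales the subscores proportionally and recomputes every strain's
#' total and rank. Reports the probability each strain keeps its baseline
#' rank, 95% percentile intervals of the totals, and the probability of
#' falling below the cutoff band. Deterministic given `seed`; a
#' `concentration` at or above the implementation cap of 1e12 returns the
#' degenerate (baseline-only) distribution.
#'
#' @param subscores a [subscore_table()] (missing cells contribute nothing).
#' @param scheme baseline [weight_scheme()]; must cover the battery's
#'   categories.
#' @param concentration positive Dirichlet concentration.
#' @param n_draws number of Monte-Carlo draws (>= 1).
#' @param seed integer RNG seed.
#' @param cutoff,band decision cutoff, as in [classify_apsi()].
#' @return object of class `sensitivity_report` with fields `n_draws`,
#'   `concentration`, `rank_stability`, `total_intervals`,
#'   `crossing_probability`, `weight_means`.
#' @export
perturb_weights <- function(subscores, scheme = default_weights(),
                            concentration = 100, n_draws = 2000, seed = 1,
                            cutoff = 50, band = 0.5) {
  stopifnot(inherits(subscores, "subscore_table"))
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  if (n_draws < 1) stop("need at least one draw", call. = FALSE)
  scheme <- weight_scheme(scheme)
  battery <- attr(subscores, "battery")
  counts <- table(battery$category)
  cats <- names(scheme)
  if (!all(names(counts) %in% cats))
    stop("scheme lacks categories: ",
         paste(setdiff(names(counts), cats), collapse = ", "), call. = FALSE)

  baseline <- rank_strains(compute_apsi(subscores, "zero", cutoff, band))
  strains <- unique(subscores$strain)

  # strain x test matrix of points (missing -> 0), aligned to the battery
  S <- matrix(0, length(strains), nrow(battery),
              dimnames = list(strains, battery$test_id))
  pts <- ifelse(subscores$missing, 0, subscores$points)
  S[cbind(subscores$strain, subscores$test_id)] <- pts

  set.seed(seed)
  W <- if (concentration >= 1e12) {
    matrix(as.numeric(scheme) / 100, n_draws, length(cats), byrow = TRUE,
           dimnames = list(NULL, cats))
  } else {
    w <- rdirichlet_gamma(n_draws, concentration * as.numeric(scheme) / 100)
    colnames(w) <- cats
    w
  }
  # per-draw rescaling factor of each test: new max / old max
  cat_idx <- match(battery$category, cats)
  factor_draws <- 100 * W[, cat_idx, drop = FALSE] /
    matrix(as.numeric(counts[battery$category]) * battery$max_score,
           n_draws, nrow(battery), byrow = TRUE)
  totals <- factor_draws %*% t(S)  # draws x strains
  colnames(totals) <- strains

  new_sensitivity_report("weight perturbation", n_draws, totals, baseline,
                         cutoff, band, seed,
                         extra = list(concentration = concentration,
                                      weight_means = colMeans(W) * 100))
}

#' Bootstrap sensitivity of totals to assay noise
#'
#' Resamples replicates with replacement within each replicate group of the
#' raw panel - plant biometry within (strain, condition) and halo diameters
#' within (strain, assay) - re-runs scoring and aggregation for each
#' resample, and reports percentile intervals of the totals, rank
#' stability against the point estimate, and cutoff-crossing
#' probabilities. Measurement families without replicate structure (fungal
#' tracks, hormone titers, qualitative outcomes) are held fixed; any group
#' with a single replicate is excluded from resampling with a warning.
#' Deterministic given `seed`.
#'
#' @param panel an [assay_panel()].
#' @param battery test definitions, as in [build_subscore_table()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @param alpha grading significance level.
#' @param missing_policy passed to [compute_apsi()].
#' @param cutoff,band decision cutoff.
#' @return object of class `sensitivity_report`.
#' @export
bootstrap_totals <- function(panel, battery = apsi_battery(), n_boot = 200,
                             seed = 1, alpha = 0.05,
                             missing_policy = "zero", cutoff = 50, band = 0.5) {
  stopifnot(inherits(panel, "assay_panel"))
  if (n_boot < 1) stop("need at least one resample", call. = FALSE)
  base_scores <- build_subscore_table(panel, battery, alpha = alpha)
  baseline <- rank_strains(compute_apsi(base_scores, missing_policy, cutoff, band))
  strains <- unique(base_scores$strain)

  plant_groups <- if (nrow(panel$plant))
    split(seq_len(nrow(panel$plant)),
          paste(panel$plant$strain, panel$plant$condition, panel$plant$day))
  else list()
  halo_groups <- if (nrow(panel$halo))
    split(seq_len(nrow(panel$halo)),
          paste(panel$halo$strain, panel$halo$assay))
  else list()
  singletons <- c(names(plant_groups)[lengths(plant_groups) == 1],
                  names(halo_groups)[lengths(halo_groups) == 1])
  if (length(singletons))
    warning("groups with a single replicate excluded from resampling: ",
            paste(singletons, collapse = "; "), call. = FALSE)

  resample_rows <- function(tab, groups, key_cols) {
    idx <- unlist(lapply(groups, function(g)
      if (length(g) == 1) g else sample(g, length(g), replace = TRUE)),
      use.names = FALSE)
    out <- tab[idx, , drop = FALSE]
    # reindex replicates so the resample is a valid panel
    grp <- do.call(paste, out[key_cols])
    out$replicate <- stats::ave(seq_along(grp), grp, FUN = seq_along)
    rownames(out) <- NULL
    out
  }

  set.seed(seed)
  totals <- matrix(NA_real_, n_boot, length(strains),
                   dimnames = list(NULL, strains))
  for (b in seq_len(n_boot)) {
    pb <- panel
    if (length(plant_groups))
      pb$plant <- resample_rows(panel$plant, plant_groups,
                                c("strain", "condition", "day"))
    if (length(halo_groups))
      pb$halo <- resample_rows(panel$halo, halo_groups, c("strain", "assay"))
    sc <- build_subscore_table(pb, battery, alpha = alpha)
    res <- compute_apsi(sc, missing_policy, cutoff, band)
    totals[b, ] <- stats::setNames(res$total, res$strain)[strains]
  }
  new_sensitivity_report("bootstrap", n_boot, totals, baseline, cutoff, band,
                         seed)
}
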