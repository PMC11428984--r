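#' The standard APSI test battery
#'
#' Eighteen tests in seven categories: four growth tests under irrigation
#' (root length, stem length, dry weight, relative water content), three
#' drought tests (RWC, root length, dry weight under withheld irrigation),
#' four dual-culture antifungal tests (antagonism and antibiosis against
#' *B. cinerea* and *F. oxysporum*), siderophore production, phosphate and
#' potassium solubilization, three phytohormone titers (IAA, IBA, GA3) and
#' urea hydrolysis. Per-test maxima come from [allocate_budgets()], i.e.
#' each category's percentage split equally over its tests; with the
#' published weights this gives maxima 5 / 9 / 7 / 4 / 4 / 3 / 4.
#'
#' @param weights a [weight_scheme()]; defaults to [default_weights()].
#' @param fungal_scheme `"tiered"` (default) or `"probit"` for the four
#'   antifungal tests.
#' @return data frame of test definitions: `test_id`, `category`, `scheme`
#'   (`tiered`, `probit` or `binary`) and `max_score`.
#' @export
apsi_battery <- function(weights = default_weights(),
                         fungal_scheme = c("tiered", "probit")) {
  fungal_scheme <- match.arg(fungal_scheme)
  def <- data.frame(
    test_id = c("root_length_pgpr", "stem_length_pgpr", "dry_weight_pgpr",
                "rwc_pgpr",
                "rwc_drought", "root_length_drought", "dry_weight_drought",
                "antagonism_b_cinerea", "antagonism_f_oxysporum",
                "antibiosis_b_cinerea", "antibiosis_f_oxysporum",
                "siderophore", "phosphate_solubilization",
                "potassium_solubilization",
                "iaa_production", "iba_production", "ga3_production",
                "urea_hydrolysis"),
    category = c(rep("growth", 4), rep("drought", 3), rep("fungal", 4),
                 "siderophore", "solubilization", "solubilization",
                 rep("hormone", 3), "urease"),
    scheme = c(rep("tiered", 7), rep(fungal_scheme, 4), "binary", "tiered",
               "binary", rep("tiered", 3), "binary"),
    stringsAsFactors = FALSE
  )
  counts <- table(def$category)
  per_test <- allocate_budgets(weights, stats::setNames(as.integer(counts),
                                                        names(counts)))
  def$max_score <- unname(per_test[def$category])
  def
}

#' Tiered (quartile) score fraction
#'
#' Maps a strain's effect onto the quartile lattice \{0, 0.25, 0.5, 0.75,
#' 1\} of its test's maximum, relative to a negative and a positive
#' reference. With r the effect ratio `(strain - negative) /
#' (positive - negative)` clipped at 0, the fraction is: 1 when the strain
#' is not significantly below the positive reference or r >= 0.75; 0.75 for
#' r in [0.5, 0.75); 0.5 for r in [0.25, 0.5); 0.25 for r in (0, 0.25)
#' provided the strain is significantly above the negative reference (or no
#' significance information is available); otherwise 0.
#'
#' @param strain_effect,negative_effect,positive_effect effect values on the
#'   raw assay scale; `positive_effect` must exceed `negative_effect`.
#' @param sig_above_negative,sig_below_positive logical or `NA` (unknown):
#'   outcome of the significance comparison against each reference, e.g.
#'   from a [compare_groups()] pairwise p-value at the working alpha. When
#'   unknown, the ratio thresholds alone decide.
#' @return fraction in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
tier_fraction <- function(strain_effect, negative_effect, positive_effect,
                          sig_above_negative = NA, sig_below_positive = NA) {
  if (positive_effect <= negative_effect)
    stop("invalid reference: positive effect must exceed negative effect",
         call. = FALSE)
  r <- max(0, (strain_effect - negative_effect) /
             (positive_effect - negative_effect))
  if (identical(sig_below_positive, FALSE) || r >= 0.75) return(1)
  if (r >= 0.5) return(0.75)
  if (r >= 0.25) return(0.5)
  if (r > 0 && !identical(sig_above_negative, FALSE)) return(0.25)
  0
}

#' Probit (cumulative-normal) score
#'
#' Continuous alternative to the quartile lattice: the score is
#' `max_score * pnorm((x - ref_mean) / ref_sd)`, strictly increasing in the
#' measurement and bounded in `(0, max_score)`. A strain at the reference
#' location scores half the maximum.
#'
#' @param x raw measurement (or standardized effect when `ref_mean = 0`,
#'   `ref_sd = 1`).
#' @param ref_mean,ref_sd reference location and scale; `ref_sd > 0`.
#' @param max_score the test's maximum points.
#' @return points in `(0, max_score)`; vectorized over `x`.
#' @examples
#' probit_score(0, 0, 1, 7)        # 3.5
#' probit_score(1.0364, 0, 1, 7)   # 5.95
#' @export
probit_score <- function(x, ref_mean, ref_sd, max_score) {
  if (ref_sd <= 0) stop("reference scale must be positive", call. = FALSE)
  max_score * stats::pnorm((x - ref_mean) / ref_sd)
}

#' Score a qualitative assay outcome
#'
#' Positive outcomes earn the full test maximum, negative outcomes zero; a
#' missing outcome stays missing (`NA`) so that the aggregation policy, not
#' the scorer, decides its treatment.
#'
#' @param outcome `"positive"`, `"negative"` or `"missing"`.
#' @param max_score the test's maximum points.
#' @return points, or `NA` for a missing outcome; vectorized.
#' @export
score_binary <- function(outcome, max_score) {
  if (!all(outcome %in% c("positive", "negative", "missing")))
    stop("outcome must be positive, negative or missing", call. = FALSE)
  ifelse(outcome == "positive", max_score,
         ifelse(outcome == "negative", 0, NA_real_))
}

#' Fungal growth inhibition
#'
#' Per-day inhibition of a fungal colony relative to the uninoculated
#' control track: `1 - d_strain(day) / d_control(day)`, clipped to `[0, 1]`,
#' summarized by its unweighted mean over the sampling days.
#'
#' @param strain_track colony diameters (cm) of the bacterium-confronted
#'   fungus, one per sampling day.
#' @param control_track control colony diameters over the same days; all
#'   strictly positive.
#' @return list with `per_day` (inhibition fractions) and `mean`.
#' @export
fungal_inhibition <- function(strain_track, control_track) {
  if (length(strain_track) != length(control_track))
    stop("strain and control tracks must cover the same days", call. = FALSE)
  if (any(control_track <= 0))
    stop("control colony diameter must be positive", call. = FALSE)
  inh <- pmin(pmax(1 - strain_track / control_track, 0), 1)
  list(per_day = inh, mean = mean(inh))
}

# -- internal: per-test raw-effect extraction -------------------------------

# What each standard test measures and where its references come from.
test_registry <- function(test_id) {
  switch(test_id,
    root_length_pgpr    = list(kind = "plant", metric = "root_length", condition = "irrigated"),
    stem_length_pgpr    = list(kind = "plant", metric = "stem_length", condition = "irrigated"),
    dry_weight_pgpr     = list(kind = "plant", metric = "dry_weight",  condition = "irrigated"),
    rwc_pgpr            = list(kind = "plant", metric = "rwc",         condition = "irrigated"),
    rwc_drought         = list(kind = "plant", metric = "rwc",         condition = "drought"),
    root_length_drought = list(kind = "plant", metric = "root_length", condition = "drought"),
    dry_weight_drought  = list(kind = "plant", metric = "dry_weight",  condition = "drought"),
    antagonism_b_cinerea   = list(kind = "fungal", fungus = "B_cinerea",   mode = "antagonism"),
    antagonism_f_oxysporum = list(kind = "fungal", fungus = "F_oxysporum", mode = "antagonism"),
    antibiosis_b_cinerea   = list(kind = "fungal", fungus = "B_cinerea",   mode = "antibiosis"),
    antibiosis_f_oxysporum = list(kind = "fungal", fungus = "F_oxysporum", mode = "antibiosis"),
    siderophore              = list(kind = "binary", assay = "siderophore"),
    phosphate_solubilization = list(kind = "halo", assay = "phosphate"),
    potassium_solubilization = list(kind = "binary", assay = "potassium_qualitative"),
    iaa_production = list(kind = "hormone", hormone = "IAA"),
    iba_production = list(kind = "hormone", hormone = "IBA"),
    ga3_production = list(kind = "hormone", hormone = "GA3"),
    urea_hydrolysis = list(kind = "binary", assay = "urease"),
    stop("unknown test_id: ", test_id, call. = FALSE)
  )
}

control_role <- function(panel, role, test_id) {
  id <- if (role %in% names(panel$controls)) panel$controls[[role]] else NULL
  if (is.null(id) || is.na(id))
    stop(sprintf("test '%s' needs a '%s' control, absent from the panel",
                 test_id, role), call. = FALSE)
  id
}

# Tier points for all panel strains of one replicate-group test
# (plant metric or halo diameter): one joint grading model, then the tier
# rule per strain against the two references.
score_replicate_test <- function(samples, neg_id, pos_id, strains, max_score,
                                 alpha, test_id) {
  if (any(lengths(samples) == 0))
    stop(sprintf("test '%s': no measurements for %s", test_id,
                 paste(names(samples)[lengths(samples) == 0], collapse = ", ")),
         call. = FALSE)
  cmp <- compare_groups(samples, alpha = alpha)
  mu <- cmp$means
  if (mu[[pos_id]] <= mu[[neg_id]])
    stop(sprintf("test '%s': positive control mean does not exceed negative",
                 test_id), call. = FALSE)
  vapply(strains, function(s) {
    sig_above <- cmp$pairwise_p[s, neg_id] < alpha && mu[[s]] > mu[[neg_id]]
    sig_below <- cmp$pairwise_p[s, pos_id] < alpha && mu[[s]] < mu[[pos_id]]
    max_score * tier_fraction(mu[[s]], mu[[neg_id]], mu[[pos_id]],
                              sig_above_negative = sig_above,
                              sig_below_positive = sig_below)
  }, numeric(1))
}

# Significance of a per-day inhibition sample against a constant reference,
# by one-sample t-test; constant samples fall back to a mean comparison.
inhibition_sig <- function(inh, mu0, alternative, alpha) {
  if (length(inh) < 2 || stats::sd(inh) == 0) {
    return(switch(alternative, greater = mean(inh) > mu0, less = mean(inh) < mu0))
  }
  stats::t.test(inh, mu = mu0, alternative = alternative)$p.value < alpha
}

#' Build the per-test subscore table
#'
#' Scores every (strain, test) pair of the battery from the raw panel:
#' tiered tests grade replicate groups through [compare_groups()] and apply
#' [tier_fraction()] against the panel's negative and positive references;
#' antifungal tests score the mean [fungal_inhibition()] against references
#' 0 (no inhibition) and 1 (complete suppression), optionally through the
#' probit map; hormone tests use the peak titer over sampling times with
#' the negative/positive control titers as references (single measurements,
#' so no significance gate); binary tests use [score_binary()]. Growth
#' tests read the irrigated condition, drought tests the drought condition.
#' Absent qualitative outcomes are recorded as missing, never as zero.
#'
#' @param panel an [assay_panel()] providing the controls each test needs.
#' @param battery test definitions, e.g. [apsi_battery()].
#' @param alpha significance level for the grading pipeline.
#' @param probit_ref for probit-scheme fungal tests: reference location and
#'   scale on the inhibition-fraction scale. The default (0.5, 1/3) centres
#'   the map on half-suppression with the endpoints of the inhibition scale
#'   at 1.5 reference SDs.
#' @return object of class `subscore_table`: data frame with columns
#'   `strain`, `test_id`, `category`, `points`, `max_score`, `missing`,
#'   carrying the battery as an attribute.
#' @export
build_subscore_table <- function(panel, battery = apsi_battery(),
                                 alpha = 0.05,
                                 probit_ref = c(mean = 0.5, sd = 1 / 3)) {
  stopifnot(inherits(panel, "assay_panel"))
  strains <- panel$strains
  rows <- vector("list", nrow(battery))
  for (t in seq_len(nrow(battery))) {
    def <- battery[t, ]
    reg <- test_registry(def$test_id)
    pts <- switch(reg$kind,
      plant = {
        neg <- control_role(panel, "plant_control", def$test_id)
        pos <- control_role(panel, "positive_control", def$test_id)
        ids <- unique(c(strains, neg, pos))
        score_replicate_test(plant_samples(panel, reg$metric, reg$condition, ids),
                             neg, pos, strains, def$max_score, alpha, def$test_id)
      },
      halo = {
        neg <- control_role(panel, "negative_control", def$test_id)
        pos <- control_role(panel, "positive_control", def$test_id)
        ids <- unique(c(strains, neg, pos))
        h <- panel$halo[panel$halo$assay == reg$assay, , drop = FALSE]
        samples <- lapply(ids, function(s) h$halo_diameter[h$strain == s])
        names(samples) <- ids
        score_replicate_test(samples, neg, pos, strains, def$max_score,
                             alpha, def$test_id)
      },
      fungal = {
        ctrl <- control_role(panel, "fungal_control", def$test_id)
        f <- panel$fungal[panel$fungal$fungus == reg$fungus &
                          panel$fungal$mode == reg$mode, , drop = FALSE]
        ctrl_track <- f[f$strain == ctrl, , drop = FALSE]
        ctrl_track <- ctrl_track[order(ctrl_track$day), , drop = FALSE]
        if (!nrow(ctrl_track))
          stop(sprintf("test '%s': no fungal control track", def$test_id),
               call. = FALSE)
        vapply(strains, function(s) {
          tr <- f[f$strain == s, , drop = FALSE]
          tr <- tr[order(tr$day), , drop = FALSE]
          if (!all(ctrl_track$day %in% tr$day))
            stop(sprintf("test '%s': strain %s does not cover the control's days",
                         def$test_id, s), call. = FALSE)
          tr <- tr[match(ctrl_track$day, tr$day), , drop = FALSE]
          inh <- fungal_inhibition(tr$colony_diameter, ctrl_track$colony_diameter)
          if (def$scheme == "probit")
            return(probit_score(inh$mean, probit_ref[["mean"]], probit_ref[["sd"]],
                                def$max_score))
          def$max_score * tier_fraction(
            inh$mean, 0, 1,
            sig_above_negative = inhibition_sig(inh$per_day, 0, "greater", alpha),
            sig_below_positive = inhibition_sig(inh$per_day, 1, "less", alpha))
        }, numeric(1))
      },
      hormone = {
        neg <- control_role(panel, "negative_control", def$test_id)
        pos <- control_role(panel, "positive_control", def$test_id)
        z <- panel$hormone[panel$hormone$hormone == reg$hormone, , drop = FALSE]
        peak <- function(s) {
          v <- z$concentration[z$strain == s]
          if (!length(v))
            stop(sprintf("test '%s': no titer for %s", def$test_id, s),
                 call. = FALSE)
          max(v)
        }
        np <- peak(neg); pp <- peak(pos)
        if (pp <= np)
          stop(sprintf("test '%s': positive control titer does not exceed negative",
                       def$test_id), call. = FALSE)
        vapply(strains, function(s)
          def$max_score * tier_fraction(peak(s), np, pp), numeric(1))
      },
      binary = {
        b <- panel$binary[panel$binary$assay == reg$assay, , drop = FALSE]
        vapply(strains, function(s) {
          out <- b$outcome[b$strain == s]
          if (!length(out)) return(NA_real_)
          score_binary(out, def$max_score)
        }, numeric(1))
      }
    )
    rows[[t]] <- data.frame(strain = strains, test_id = def$test_id,
                            category = def$category, points = unname(pts),
                            max_score = def$max_score,
                            missing = is.na(pts), stringsAsFactors = FALSE)
  }
  subscore_table(do.call(rbind, rows), battery)
}

#' Construct a subscore table
#'
#' Validates a long table of per-test points against its battery: every
#' non-missing score must lie in `[0, max_score]` and reference a battery
#' test.
#'
#' @param entries data frame with columns `strain`, `test_id`, `points`,
#'   and optionally `category`, `max_score`, `missing` (derived from the
#'   battery when absent; `missing` defaults to `is.na(points)`).
#' @param battery test-definition data frame (see [apsi_battery()]).
#' @return object of class `subscore_table`.
#' @export
subscore_table <- function(entries, battery = apsi_battery()) {
  entries <- as.data.frame(entries)
  bad <- setdiff(entries$test_id, battery$test_id)
  if (length(bad))
    stop("subscores reference unknown tests: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  i <- match(entries$test_id, battery$test_id)
  if (is.null(entries$category)) entries$category <- battery$category[i]
  if (is.null(entries$max_score)) entries$max_score <- battery$max_score[i]
  if (is.null(entries$missing)) entries$missing <- is.na(entries$points)
  ok <- entries$missing | (entries$points >= -1e-9 &
                           entries$points <= entries$max_score + 1e-9)
  if (any(!ok))
    stop("points outside [0, max] for: ",
         paste(unique(paste(entries$strain[!ok], entries$test_id[!ok])),
               collapse = ", "), call. = FALSE)
  structure(entries, battery = battery,
            class = c("subscore_table", "data.frame"))
}

#' Read / write subscore tables
#'
#' CSV exchange format with columns `strain, test_id, points, max, missing`;
#' missing cells carry an empty `points` field and `missing = TRUE`.
#'
#' @param path CSV path.
#' @param battery battery to validate against.
#' @return [subscore_table()] (for `read_subscores`); `path` invisibly (for
#'   `write_subscores`).
#' @export
read_subscores <- function(path, battery = apsi_battery()) {
  if (!file.exists(path)) stop("subscore file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty subscore table: ", path, call. = FALSE)
  names(tab)[names(tab) == "max"] <- "max_score"
  tab$missing <- as.logical(tab$missing)
  tab$points <- as.numeric(tab$points)
  subscore_table(tab, battery)
}

#' @rdname read_subscores
#' @param subscores a [subscore_table()].
#' @export
write_subscores <- function(subscores, path) {
  out <- data.frame(strain = subscores$strain, test_id = subscores$test_id,
                    points = ifelse(subscores$missing, "", subscores$points),
                    max = subscores$max_score, missing = subscores$missing)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
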