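#' Assay panels: the raw-measurement container
#'
#' An `assay_panel` holds all raw replicate measurements for a set of
#' bacterial strains plus their controls: plant biometry under irrigated and
#' drought conditions, dual-culture fungal colony diameters, solubilization
#' halo diameters, phytohormone titers, and qualitative (binary) assay
#' outcomes. It is the single input object for trait classification
#' ([classify_strain_traits()]) and scoring ([build_subscore_table()]).
#'
#' Units are fixed package-wide: grams for masses, centimeters for lengths
#' and diameters, micrograms per litre for hormone titers, hours for
#' incubation times and days for sampling days. Loaders reject any other
#' unit annotation.
#'
#' @param strains character vector of strain identifiers under evaluation.
#' @param controls named character vector mapping control roles to strain
#'   identifiers. Recognised roles: `plant_control` (non-inoculated plants),
#'   `positive_control` (reference PGPR, e.g. a *P. putida* strain),
#'   `negative_control` (non-solubilizing / non-producing organism) and
#'   `fungal_control` (uninoculated fungal track).
#' @param plant data frame with columns `strain`, `condition`
#'   (`"irrigated"`/`"drought"`), `day`, `replicate`, `fresh_weight`,
#'   `dry_weight`, `turgid_weight`, `root_length`, `stem_length`.
#' @param fungal data frame with columns `strain`, `fungus`
#'   (`"F_oxysporum"`/`"B_cinerea"`), `mode` (`"antagonism"`/`"antibiosis"`),
#'   `day` (5, 10 or 15), `colony_diameter`.
#' @param halo data frame with columns `strain`, `assay`
#'   (`"phosphate"`/`"potassium"`), `replicate`, `halo_diameter`.
#' @param hormone data frame with columns `strain`, `hormone`
#'   (`"IAA"`/`"IBA"`/`"GA3"`), `time_h` (24 or 72), `concentration`.
#' @param binary data frame with columns `strain`, `assay` (`"siderophore"`,
#'   `"urease"`, `"potassium_qualitative"`), `outcome` (`"positive"`,
#'   `"negative"`, `"missing"`). A missing outcome is a first-class state,
#'   distinct from negative.
#' @return An object of class `assay_panel`.
#' @export
assay_panel <- function(strains, controls = character(),
                        plant = NULL, fungal = NULL, halo = NULL,
                        hormone = NULL, binary = NULL) {
  empty <- function(cols) {
    out <- lapply(cols, function(x) if (x %in% c("strain", "condition", "fungus",
                                                 "mode", "assay", "hormone", "outcome"))
      character() else numeric())
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  panel <- structure(list(
    strains  = as.character(strains),
    controls = controls,
    plant    = if (is.null(plant)) empty(c("strain", "condition", "day", "replicate",
                                           "fresh_weight", "dry_weight", "turgid_weight",
                                           "root_length", "stem_length")) else as.data.frame(plant),
    fungal   = if (is.null(fungal)) empty(c("strain", "fungus", "mode", "day",
                                            "colony_diameter")) else as.data.frame(fungal),
    halo     = if (is.null(halo)) empty(c("strain", "assay", "replicate",
                                          "halo_diameter")) else as.data.frame(halo),
    hormone  = if (is.null(hormone)) empty(c("strain", "hormone", "time_h",
                                             "concentration")) else as.data.frame(hormone),
    binary   = if (is.null(binary)) empty(c("strain", "assay", "outcome")) else as.data.frame(binary)
  ), class = "assay_panel")
  validate_panel(panel)
}

#' Validate an assay panel
#'
#' Checks enum fields strictly, non-negativity of every measurement,
#' membership of every measurement's strain in `strains` or `controls`, and
#' uniqueness of replicate keys. Called by [assay_panel()] and
#' [load_panel()].
#'
#' @param panel an `assay_panel`.
#' @return The panel, invisibly validated (errors describe offending rows).
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  known <- c(panel$strains, unname(panel$controls))
  bad_rows <- function(tab, ok, what) {
    if (nrow(tab) && any(!ok))
      stop(sprintf("invalid %s in rows: %s", what,
                   paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  with(panel, {
    bad_rows(plant, plant$strain %in% known, "plant strain (not in panel)")
    bad_rows(plant, plant$condition %in% c("irrigated", "drought"), "plant condition")
    num <- c("fresh_weight", "dry_weight", "turgid_weight", "root_length", "stem_length")
    for (v in num) bad_rows(plant, is.finite(plant[[v]]) & plant[[v]] >= 0,
                            paste("plant", v, "(negative or non-numeric)"))
    bad_rows(plant, plant$day >= 0, "plant day")

    bad_rows(fungal, fungal$strain %in% c(known), "fungal strain (not in panel)")
    bad_rows(fungal, fungal$fungus %in% c("F_oxysporum", "B_cinerea"), "fungus")
    bad_rows(fungal, fungal$mode %in% c("antagonism", "antibiosis"), "fungal mode")
    bad_rows(fungal, fungal$day %in% c(5, 10, 15), "fungal sampling day")
    bad_rows(fungal, is.finite(fungal$colony_diameter) & fungal$colony_diameter >= 0,
             "colony diameter")

    bad_rows(halo, halo$strain %in% known, "halo strain (not in panel)")
    bad_rows(halo, halo$assay %in% c("phosphate", "potassium"), "halo assay")
    bad_rows(halo, is.finite(halo$halo_diameter) & halo$halo_diameter >= 0, "halo diameter")

    bad_rows(hormone, hormone$strain %in% known, "hormone strain (not in panel)")
    bad_rows(hormone, hormone$hormone %in% c("IAA", "IBA", "GA3"), "hormone")
    bad_rows(hormone, hormone$time_h %in% c(24, 72), "hormone time")
    bad_rows(hormone, is.finite(hormone$concentration) & hormone$concentration >= 0,
             "hormone concentration")

    bad_rows(binary, binary$strain %in% known, "binary-assay strain (not in panel)")
    bad_rows(binary, binary$assay %in% c("siderophore", "urease", "potassium_qualitative"),
             "binary assay")
    bad_rows(binary, binary$outcome %in% c("positive", "negative", "missing"),
             "binary outcome")
  })
  dup <- function(tab, keys, what) {
    if (nrow(tab)) {
      k <- do.call(paste, c(tab[keys], sep = "\r"))
      if (anyDuplicated(k))
        stop(sprintf("duplicate %s keys in rows: %s", what,
                     paste(which(duplicated(k)), collapse = ", ")), call. = FALSE)
    }
  }
  dup(panel$plant, c("strain", "condition", "day", "replicate"), "plant measurement")
  dup(panel$fungal, c("strain", "fungus", "mode", "day"), "fungal measurement")
  dup(panel$halo, c("strain", "assay", "replicate"), "halo measurement")
  dup(panel$hormone, c("strain", "hormone", "time_h"), "hormone measurement")
  dup(panel$binary, c("strain", "assay"), "binary outcome")
  invisible(panel)
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("Assay panel:", length(x$strains), "strains (",
      paste(x$strains, collapse = ", "), ")\n")
  if (length(x$controls))
    cat("  controls:", paste(names(x$controls), x$controls, sep = " = ",
                             collapse = "; "), "\n")
  cat(sprintf("  plant: %d  fungal: %d  halo: %d  hormone: %d  binary: %d rows\n",
              nrow(x$plant), nrow(x$fungal), nrow(x$halo),
              nrow(x$hormone), nrow(x$binary)))
  invisible(x)
}

#' Relative water content
#'
#' RWC = (FW - DW) / (TW - DW), the dimensionless hydration state of a plant
#' sample: fresh weight relative to dry and fully turgid weight. Equals 1 at
#' full turgor and 0 when fully dry.
#'
#' @param fw fresh weight (g).
#' @param dw dry weight (g).
#' @param tw fully turgid weight (g).
#' @param clip if `TRUE`, fresh weights marginally outside `[dw, tw]`
#'   (measurement noise) are clamped into range with a warning; the default
#'   is an error, since by procedure `dw <= fw <= tw`.
#' @return RWC as a fraction in `[0, 1]`; vectorized over its arguments.
#' @examples
#' compute_rwc(2, 1, 3)   # 0.5
#' @export
compute_rwc <- function(fw, dw, tw, clip = FALSE) {
  if (any(tw <= dw))
    stop("degenerate denominator: turgid weight must exceed dry weight", call. = FALSE)
  out_of_range <- fw < dw | fw > tw
  if (any(out_of_range)) {
    if (!clip)
      stop("fresh weight outside [dry, turgid] range; use clip = TRUE to clamp",
           call. = FALSE)
    warning("fresh weight outside [dry, turgid] clamped", call. = FALSE)
    fw <- pmin(pmax(fw, dw), tw)
  }
  (fw - dw) / (tw - dw)
}

# End-of-trial plant rows (largest sampling day per condition), with RWC.
plant_at_end <- function(panel, condition) {
  p <- panel$plant[panel$plant$condition == condition, , drop = FALSE]
  if (!nrow(p)) return(p)
  p <- p[p$day == max(p$day), , drop = FALSE]
  p$rwc <- compute_rwc(p$fresh_weight, p$dry_weight, p$turgid_weight, clip = TRUE)
  p
}

# Named list of per-strain samples of one plant metric.
plant_samples <- function(panel, metric, condition, ids) {
  p <- plant_at_end(panel, condition)
  out <- lapply(ids, function(s) p[[metric]][p$strain == s])
  names(out) <- ids
  out
}

#' Classify PGPR and drought-protectant traits
#'
#' A strain is flagged as plant-growth promoting (PGPR) when its combined
#' root plus stem length under irrigation exceeds that of the non-inoculated
#' plant control; it is flagged as drought protectant when both its dry
#' weight and its relative water content under drought exceed the control.
#' By default exceedance must be statistically significant at `alpha`
#' (Tukey HSD within the grading pipeline of [compare_groups()]); set
#' `method = "raw"` to compare group means directly.
#'
#' @param panel an `assay_panel` with a `plant_control` role.
#' @param alpha significance level (default 0.05).
#' @param method `"significance"` (default) or `"raw"`.
#' @return data frame with columns `strain`, `is_pgpr`,
#'   `is_drought_protectant`.
#' @export
classify_strain_traits <- function(panel, alpha = 0.05,
                                   method = c("significance", "raw")) {
  method <- match.arg(method)
  ctrl <- if ("plant_control" %in% names(panel$controls))
    panel$controls[["plant_control"]] else NULL
  if (is.null(ctrl) || is.na(ctrl))
    stop("panel has no plant_control role; cannot classify traits", call. = FALSE)
  ids <- c(panel$strains, ctrl)

  exceeds <- function(metric, condition) {
    p <- plant_at_end(panel, condition)
    if (metric == "combined_length") p$combined_length <- p$root_length + p$stem_length
    samples <- lapply(ids, function(s) p[[metric]][p$strain == s])
    names(samples) <- ids
    if (any(lengths(samples) == 0))
      stop("missing plant measurements for: ",
           paste(ids[lengths(samples) == 0], collapse = ", "), call. = FALSE)
    mu <- vapply(samples, mean, numeric(1))
    higher <- mu[panel$strains] > mu[[ctrl]]
    if (method == "raw") return(higher)
    cmp <- compare_groups(samples, alpha = alpha)
    sig <- cmp$pairwise_p[panel$strains, ctrl] < alpha
    higher & sig
  }

  data.frame(
    strain = panel$strains,
    is_pgpr = unname(exceeds("combined_length", "irrigated")),
    is_drought_protectant = unname(exceeds("dry_weight", "drought") &
                                     exceeds("rwc", "drought")),
    stringsAsFactors = FALSE
  )
}
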