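#' Read an assay panel from long-format CSV
#'
#' The exchange format is one UTF-8 CSV with '.' as decimal separator and
#' columns `strain, assay, condition, fungus, mode, hormone, day, time_h,
#' replicate, value, unit`; columns that do not apply to a row are left
#' empty. Row assays:
#' \describe{
#'   \item{plant biometry}{`assay` one of `fresh_weight`, `dry_weight`,
#'     `turgid_weight`, `root_length`, `stem_length`; needs `condition`,
#'     `day`, `replicate`; unit `g` or `cm`.}
#'   \item{fungal}{`assay = colony_diameter`; needs `fungus`, `mode`, `day`;
#'     unit `cm`.}
#'   \item{halos}{`assay` `phosphate` or `potassium`; needs `replicate`;
#'     unit `cm`.}
#'   \item{hormones}{`assay = hormone`; needs `hormone`, `time_h`; unit
#'     `ug/L`.}
#'   \item{binary}{`assay` `siderophore`, `urease` or
#'     `potassium_qualitative`; `value` is `positive`, `negative` or
#'     `missing`; unit empty.}
#' }
#'
#' @param path path to the panel CSV.
#' @param config optional test configuration (see [load_test_config()])
#'   supplying `strains` and `controls`; when absent, every identifier in
#'   the file becomes a panel strain and no controls are declared.
#' @return a validated [assay_panel()].
#' @export
load_panel <- function(path, config = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = character())
  needed <- c("strain", "assay", "condition", "fungus", "mode", "hormone",
              "day", "time_h", "replicate", "value", "unit")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("panel file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  rown <- seq_len(nrow(raw)) + 1L  # file line numbers (header = line 1)
  fail <- function(which, msg)
    stop(sprintf("%s (file line%s %s)", msg, if (length(which) > 1) "s" else "",
                 paste(rown[which], collapse = ", ")), call. = FALSE)

  plant_assays <- c("fresh_weight", "dry_weight", "turgid_weight",
                    "root_length", "stem_length")
  binary_assays <- c("siderophore", "urease", "potassium_qualitative")
  known_assays <- c(plant_assays, "colony_diameter", "phosphate", "potassium",
                    "hormone", binary_assays)
  bad <- !(raw$assay %in% known_assays)
  if (any(bad)) fail(which(bad), paste0("unknown assay name '",
                                        raw$assay[which(bad)[1]], "'"))

  num <- function(x, idx, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- idx & (is.na(v) | !is.finite(v))
    if (any(bad)) fail(which(bad), paste("non-numeric", what))
    neg <- idx & !is.na(v) & v < 0
    if (any(neg)) fail(which(neg), paste("negative", what))
    v
  }
  check_unit <- function(idx, expected) {
    bad <- idx & !(raw$unit %in% expected)
    if (any(bad))
      fail(which(bad), sprintf("unit must be one of {%s}",
                               paste(expected, collapse = ", ")))
  }

  is_plant <- raw$assay %in% plant_assays
  is_fungal <- raw$assay == "colony_diameter"
  is_halo <- raw$assay %in% c("phosphate", "potassium")
  is_horm <- raw$assay == "hormone"
  is_bin <- raw$assay %in% binary_assays

  check_unit(is_plant & raw$assay %in% c("fresh_weight", "dry_weight", "turgid_weight"), "g")
  check_unit(is_plant & raw$assay %in% c("root_length", "stem_length"), "cm")
  check_unit(is_fungal | is_halo, "cm")
  check_unit(is_horm, "ug/L")
  check_unit(is_bin, "")

  bad_cond <- is_plant & !(raw$condition %in% c("irrigated", "drought"))
  if (any(bad_cond))
    fail(which(bad_cond), sprintf("unknown condition '%s'",
                                  raw$condition[which(bad_cond)[1]]))

  value <- rep(NA_real_, nrow(raw))
  value[!is_bin] <- num(raw$value, !is_bin, "value")[!is_bin]
  bad_out <- is_bin & !(raw$value %in% c("positive", "negative", "missing"))
  if (any(bad_out)) fail(which(bad_out), "binary outcome must be positive/negative/missing")

  plant_long <- data.frame(strain = raw$strain[is_plant],
                           condition = raw$condition[is_plant],
                           day = num(raw$day, is_plant, "day")[is_plant],
                           replicate = num(raw$replicate, is_plant, "replicate")[is_plant],
                           metric = raw$assay[is_plant],
                           value = value[is_plant], stringsAsFactors = FALSE)
  plant <- NULL
  if (nrow(plant_long)) {
    wide <- stats::reshape(plant_long, idvar = c("strain", "condition", "day", "replicate"),
                           timevar = "metric", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    for (m in plant_assays) if (!m %in% names(wide)) wide[[m]] <- NA_real_
    if (anyNA(wide[plant_assays]))
      stop("incomplete plant biometry: every (strain, condition, day, replicate) ",
           "needs all five metrics", call. = FALSE)
    plant <- wide[c("strain", "condition", "day", "replicate", plant_assays)]
    rownames(plant) <- NULL
  }

  fungal <- if (any(is_fungal)) {
    bad_f <- is_fungal & !(raw$fungus %in% c("F_oxysporum", "B_cinerea"))
    if (any(bad_f)) fail(which(bad_f), "unknown fungus")
    bad_m <- is_fungal & !(raw$mode %in% c("antagonism", "antibiosis"))
    if (any(bad_m)) fail(which(bad_m), "unknown fungal mode")
    data.frame(strain = raw$strain[is_fungal], fungus = raw$fungus[is_fungal],
               mode = raw$mode[is_fungal],
               day = num(raw$day, is_fungal, "day")[is_fungal],
               colony_diameter = value[is_fungal], stringsAsFactors = FALSE)
  } else NULL

  halo <- if (any(is_halo)) {
    data.frame(strain = raw$strain[is_halo], assay = raw$assay[is_halo],
               replicate = num(raw$replicate, is_halo, "replicate")[is_halo],
               halo_diameter = value[is_halo], stringsAsFactors = FALSE)
  } else NULL

  hormone <- if (any(is_horm)) {
    bad_h <- is_horm & !(raw$hormone %in% c("IAA", "IBA", "GA3"))
    if (any(bad_h)) fail(which(bad_h), "unknown hormone")
    data.frame(strain = raw$strain[is_horm], hormone = raw$hormone[is_horm],
               time_h = num(raw$time_h, is_horm, "time_h")[is_horm],
               concentration = value[is_horm], stringsAsFactors = FALSE)
  } else NULL

  binary <- if (any(is_bin)) {
    data.frame(strain = raw$strain[is_bin], assay = raw$assay[is_bin],
               outcome = raw$value[is_bin], stringsAsFactors = FALSE)
  } else NULL

  controls <- if (!is.null(config)) config$controls else character()
  strains <- if (!is.null(config) && !is.null(config$strains)) config$strains
             else setdiff(unique(raw$strain), unname(controls))
  assay_panel(strains = strains, controls = controls, plant = plant,
              fungal = fungal, halo = halo, hormone = hormone, binary = binary)
}

#' Write an assay panel to long-format CSV
#'
#' Inverse of [load_panel()]: emits the long exchange format so that a
#' written panel reloads identically (up to row order and float formatting).
#'
#' @param panel an `assay_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  blank <- function(n) rep("", n)
  rows <- list()
  p <- panel$plant
  if (nrow(p)) {
    for (m in c("fresh_weight", "dry_weight", "turgid_weight", "root_length",
                "stem_length"))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = p$strain, assay = m, condition = p$condition, fungus = blank(nrow(p)),
        mode = blank(nrow(p)), hormone = blank(nrow(p)), day = p$day,
        time_h = blank(nrow(p)), replicate = p$replicate,
        value = as.character(p[[m]]),
        unit = if (m %in% c("root_length", "stem_length")) "cm" else "g",
        stringsAsFactors = FALSE)
  }
  f <- panel$fungal
  if (nrow(f))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = f$strain, assay = "colony_diameter", condition = blank(nrow(f)),
      fungus = f$fungus, mode = f$mode, hormone = blank(nrow(f)), day = f$day,
      time_h = blank(nrow(f)), replicate = blank(nrow(f)),
      value = as.character(f$colony_diameter), unit = "cm", stringsAsFactors = FALSE)
  h <- panel$halo
  if (nrow(h))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = h$strain, assay = h$assay, condition = blank(nrow(h)),
      fungus = blank(nrow(h)), mode = blank(nrow(h)), hormone = blank(nrow(h)),
      day = blank(nrow(h)), time_h = blank(nrow(h)), replicate = h$replicate,
      value = as.character(h$halo_diameter), unit = "cm", stringsAsFactors = FALSE)
  z <- panel$hormone
  if (nrow(z))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = z$strain, assay = "hormone", condition = blank(nrow(z)),
      fungus = blank(nrow(z)), mode = blank(nrow(z)), hormone = z$hormone,
      day = blank(nrow(z)), time_h = z$time_h, replicate = blank(nrow(z)),
      value = as.character(z$concentration), unit = "ug/L", stringsAsFactors = FALSE)
  b <- panel$binary
  if (nrow(b))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = b$strain, assay = b$assay, condition = blank(nrow(b)),
      fungus = blank(nrow(b)), mode = blank(nrow(b)), hormone = blank(nrow(b)),
      day = blank(nrow(b)), time_h = blank(nrow(b)), replicate = blank(nrow(b)),
      value = b$outcome, unit = "", stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(), assay = character(), condition = character(),
               fungus = character(), mode = character(), hormone = character(),
               day = character(), time_h = character(), replicate = character(),
               value = character(), unit = character())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a test-battery configuration
#'
#' The YAML configuration declares the strains under evaluation, the control
#' roles, the category weights (percent of the index) and, optionally, an
#' explicit battery. When the battery is omitted it is built from the
#' weights by [apsi_battery()].
#'
#' @param path path to a YAML file with top-level keys `strains`, `controls`,
#'   `weights` and optionally `battery` (list of `test_id`, `category`,
#'   `scheme`, `max_score` records).
#' @return list with elements `strains`, `controls`, `weights`
#'   (a [weight_scheme()]) and `battery` (a test-definition data frame).
#' @export
load_test_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  weights <- if (!is.null(cfg$weights)) weight_scheme(unlist(cfg$weights))
             else default_weights()
  battery <- if (!is.null(cfg$battery)) {
    do.call(rbind, lapply(cfg$battery, function(b)
      data.frame(test_id = b$test_id, category = b$category, scheme = b$scheme,
                 max_score = as.numeric(b$max_score), stringsAsFactors = FALSE)))
  } else apsi_battery(weights)
  list(strains = as.character(cfg$strains),
       controls = unlist(cfg$controls),
       weights = weights, battery = battery)
}
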