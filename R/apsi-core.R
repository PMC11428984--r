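#' Aggregate subscores into the 0-100 index
#'
#' Sums every strain's per-test points into its index total and category
#' breakdown, then applies the suitability cutoff. Missing tests either
#' contribute nothing (`missing_policy = "zero"`, the default: a blank cell
#' simply earns no points) or the total is rescaled to the attainable
#' maximum (`"renormalize"`: `total / attainable * 100`).
#'
#' @param subscores a [subscore_table()].
#' @param missing_policy `"zero"` or `"renormalize"`.
#' @param cutoff,band suitability cutoff (default 50 +/- 0.5); see
#'   [classify_apsi()].
#' @return object of class `apsi_result`: data frame with one row per
#'   strain (`strain`, `total`, `classification`, one `cat_*` column per
#'   category, `n_missing`) plus a `missing_tests` attribute (named list)
#'   and the battery.
#' @export
compute_apsi <- function(subscores, missing_policy = c("zero", "renormalize"),
                         cutoff = 50, band = 0.5) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(subscores, "subscore_table"))
  battery <- attr(subscores, "battery")
  full_max <- sum(battery$max_score)
  if (missing_policy == "zero" && abs(full_max - 100) > 1e-9)
    warning("battery maxima sum to ", full_max,
            ", not 100; totals are on the battery's own scale", call. = FALSE)

  strains <- unique(subscores$strain)
  cats <- unique(battery$category)
  pts <- ifelse(subscores$missing, 0, subscores$points)

  by_cat <- matrix(0, length(strains), length(cats),
                   dimnames = list(strains, cats))
  agg <- stats::aggregate(pts, by = list(strain = subscores$strain,
                                         category = subscores$category), FUN = sum)
  by_cat[cbind(agg$strain, agg$category)] <- agg$x
  total <- rowSums(by_cat)

  missing_tests <- lapply(strains, function(s)
    subscores$test_id[subscores$strain == s & subscores$missing])
  names(missing_tests) <- strains

  if (missing_policy == "renormalize") {
    attainable <- vapply(strains, function(s) {
      sub <- subscores[subscores$strain == s, ]
      sum(sub$max_score[!sub$missing])
    }, numeric(1))
    scale <- ifelse(attainable > 0, 100 / attainable, 0)
    total <- total * scale
    by_cat <- by_cat * scale
  }

  out <- data.frame(strain = strains, total = unname(total),
                    classification = classify_apsi(total, cutoff, band),
                    stringsAsFactors = FALSE)
  colnames(by_cat) <- paste0("cat_", colnames(by_cat))
  out <- cbind(out, as.data.frame(by_cat, stringsAsFactors = FALSE))
  out$n_missing <- lengths(missing_tests)[out$strain]
  rownames(out) <- NULL
  structure(out, missing_tests = missing_tests, battery = battery,
            cutoff = cutoff, band = band,
            class = c("apsi_result", "data.frame"))
}

#' Suitability classification
#'
#' Three-way decision on an index total with cutoff 50 and half-width 0.5:
#' totals below `cutoff - band` indicate the strain needs more tests before
#' it can be considered suitable, totals within the band are borderline,
#' and totals above `cutoff + band` are suitable. The published rule does
#' not say on which side an exact 50 falls, so the band is an explicit
#' class rather than a silent tie-break.
#'
#' @param total index total(s) in `[0, 100]`.
#' @param cutoff decision cutoff (points).
#' @param band half-width of the borderline band (points, >= 0).
#' @return character vector: `"needs_more_tests"`, `"borderline"` or
#'   `"suitable"`.
#' @export
classify_apsi <- function(total, cutoff = 50, band = 0.5) {
  if (band < 0) stop("band must be non-negative", call. = FALSE)
  ifelse(total < cutoff - band, "needs_more_tests",
         ifelse(total > cutoff + band, "suitable", "borderline"))
}

#' Rank strains by index total
#'
#' Orders strains by descending total with competition ranking: strains
#' whose totals differ by less than `tol` share the lower rank number, and
#' the following strain takes the rank it would have with the tie counted
#' (1, 1, 3, ...). Display order among exact ties is stable with respect to
#' the input order.
#'
#' @param results an `apsi_result` (or any data frame with `strain` and
#'   `total` columns).
#' @param tol absolute tie tolerance on totals.
#' @return the input rows ordered by descending total with added `rank` and
#'   `tied` columns.
#' @export
rank_strains <- function(results, tol = 1e-9) {
  if (!nrow(results)) stop("no results to rank", call. = FALSE)
  ord <- order(-results$total)
  out <- results[ord, , drop = FALSE]
  n <- nrow(out)
  rank <- integer(n)
  rank[1] <- 1L
  for (i in seq_len(n)[-1])
    rank[i] <- if (abs(out$total[i] - out$total[i - 1]) < tol) rank[i - 1] else i
  out$rank <- rank
  out$tied <- rank %in% rank[duplicated(rank)]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.apsi_result <- function(x, digits = 4, ...) {
  cat(sprintf("APSI results (%d strains, cutoff %g +/- %g):\n",
              nrow(x), attr(x, "cutoff"), attr(x, "band")))
  tab <- data.frame(strain = x$strain, total = round(x$total, digits),
                    classification = x$classification,
                    missing = x$n_missing)
  print(tab[order(-tab$total), ], row.names = FALSE)
  invisible(x)
}
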