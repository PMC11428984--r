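#' Category weight scheme
#'
#' A named vector of category percentages summing to 100: the share of the
#' 0-100 index carried by each assay category.
#'
#' @param weights named numeric vector, each entry >= 0, summing to 100
#'   within 1e-9.
#' @return object of class `weight_scheme`.
#' @seealso [default_weights()] for the published scheme.
#' @export
weight_scheme <- function(weights) {
  weights <- unlist(weights)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by category", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 100) > 1e-9)
    stop("weights must sum to 100 (got ", sum(weights), ")", call. = FALSE)
  structure(weights, class = "weight_scheme")
}

#' The published category weights
#'
#' Growth stimulation in the absence of stress 20%, drought protection 27%,
#' protection from phytopathogenic fungi 28%, phosphorus/potassium
#' solubilization 8%, siderophore production 4% and urea hydrolysis 4%.
#' These stated shares sum to 91; the remaining 9% is the phytohormone
#' category, recovered from the score table's three hormone tests at 3
#' points each (an inference, since the hormone share is not stated
#' explicitly alongside the others).
#'
#' @return a [weight_scheme()].
#' @export
default_weights <- function() {
  weight_scheme(c(growth = 20, drought = 27, fungal = 28, hormone = 9,
                  solubilization = 8, siderophore = 4, urease = 4))
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Category weights (% of index):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Allocate category weights to per-test maxima
#'
#' Splits each category's percentage equally across its tests: a category
#' worth w% with k tests gives each test a maximum score of w/k points, so
#' that the battery's maxima sum back to 100.
#'
#' @param scheme a [weight_scheme()].
#' @param counts named integer vector: number of tests per category. Every
#'   category with positive weight must appear with >= 1 test.
#' @return named numeric vector of per-test maxima, one entry per category.
#' @examples
#' allocate_budgets(default_weights(),
#'                  c(growth = 4, drought = 3, fungal = 4, hormone = 3,
#'                    solubilization = 2, siderophore = 1, urease = 1))
#' @export
allocate_budgets <- function(scheme, counts) {
  scheme <- weight_scheme(scheme)
  missing_cat <- setdiff(names(scheme)[as.numeric(scheme) > 0], names(counts))
  if (length(missing_cat) || any(counts[names(scheme)[as.numeric(scheme) > 0]] < 1, na.rm = TRUE))
    stop("categories with positive weight but no tests: ",
         paste(c(missing_cat,
                 intersect(names(counts)[counts < 1], names(scheme))), collapse = ", "),
         call. = FALSE)
  out <- as.numeric(scheme) / as.numeric(counts[names(scheme)])
  stats::setNames(out, names(scheme))
}

#' Delphi panel state
#'
#' Holds one round of a Delphi weight-elicitation exercise: the per-expert
#' category weight vectors, their component-wise median aggregate, and the
#' per-component interquartile range as the dispersion (consensus) measure.
#'
#' @param experts numeric matrix, one row per expert and one column per
#'   category; every row must sum to 100 (within 1e-6).
#' @param round round counter (0 for the initial elicitation).
#' @return object of class `delphi_state`.
#' @export
delphi_state <- function(experts, round = 0L) {
  experts <- as.matrix(experts)
  if (nrow(experts) < 1) stop("empty expert set", call. = FALSE)
  if (is.null(colnames(experts)))
    colnames(experts) <- paste0("cat", seq_len(ncol(experts)))
  sums <- rowSums(experts)
  if (any(abs(sums - 100) > 1e-6))
    stop("every expert weight vector must sum to 100", call. = FALSE)
  structure(list(
    round = as.integer(round),
    experts = experts,
    aggregate = apply(experts, 2, stats::median),
    dispersion = apply(experts, 2, stats::IQR)
  ), class = "delphi_state")
}

#' @export
print.delphi_state <- function(x, ...) {
  cat(sprintf("Delphi state: round %d, %d experts, max IQR %.3g\n",
              x$round, nrow(x$experts), max(x$dispersion)))
  print(rbind(aggregate = x$aggregate, IQR = x$dispersion))
  invisible(x)
}

#' One Delphi round
#'
#' The aggregate is the component-wise median of the expert vectors; each
#' expert then moves toward the aggregate by the fraction `contraction`
#' (their revised opinion after seeing the panel summary) and is
#' renormalized to sum to 100. Dispersion (per-component IQR) is
#' recomputed; `contraction = 0` leaves the experts unchanged.
#'
#' @param state a [delphi_state()] with >= 2 experts.
#' @param contraction fraction in `[0, 1]`.
#' @return the next `delphi_state` (round incremented).
#' @export
delphi_round <- function(state, contraction = 0.5) {
  stopifnot(inherits(state, "delphi_state"))
  if (nrow(state$experts) < 2) stop("need at least 2 experts", call. = FALSE)
  if (contraction < 0 || contraction > 1)
    stop("contraction must lie in [0, 1]", call. = FALSE)
  agg <- apply(state$experts, 2, stats::median)
  moved <- state$experts + contraction *
    (matrix(agg, nrow(state$experts), ncol(state$experts), byrow = TRUE) - state$experts)
  moved <- moved / rowSums(moved) * 100
  delphi_state(moved, round = state$round + 1L)
}

#' Iterate Delphi rounds to consensus
#'
#' Applies [delphi_round()] until every component's interquartile range
#' falls below `tolerance`, or `max_rounds` is reached. The returned scheme
#' is the final aggregate, renormalized to sum to 100; non-convergence sets
#' the `converged` attribute to `FALSE` with a warning.
#'
#' @param initial a [delphi_state()].
#' @param tolerance IQR bound per category (percentage points).
#' @param max_rounds iteration cap.
#' @param contraction per-round movement fraction.
#' @return a [weight_scheme()] with attributes `rounds` and `converged`.
#' @export
delphi_converge <- function(initial, tolerance = 0.1, max_rounds = 100,
                            contraction = 0.5) {
  stopifnot(inherits(initial, "delphi_state"))
  state <- initial
  converged <- FALSE
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    state <- delphi_round(state, contraction)
    rounds <- r
    if (max(state$dispersion) < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Delphi panel did not reach consensus in ", max_rounds, " rounds",
            call. = FALSE)
  agg <- state$aggregate / sum(state$aggregate) * 100
  out <- weight_scheme(agg)
  attr(out, "rounds") <- rounds
  attr(out, "converged") <- converged
  out
}
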