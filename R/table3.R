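#' The packaged four-strain reference score table
#'
#' The package ships, as plain CSV under `extdata`, the published per-test
#' score table for the four evaluated *Bacillus* strains: the isolate
#' *B. velezensis* A6 and the commercial strains *B. amyloliquefaciens*
#' FZB42, DSM7 (Fukumoto) and D747. Eighteen tests with maxima
#' 5/9/7/4/4/3/4 per category, four subscore columns (the FZB42 urea cell
#' is blank, i.e. missing), and the four printed totals 78.95, 67.75, 61.5
#' and 65.25. Loading validates that each column re-sums (missing as 0) to
#' its stored total.
#'
#' @return list with elements `battery` (test definitions), `scores` (a
#'   [subscore_table()] in long form), `totals` (named published totals)
#'   and `strains` (in the published column order).
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_scores.csv", package = "apsi",
                      mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  strains <- c("A6", "FZB42", "DSM7", "D747")
  battery <- wide[c("test_id", "category", "scheme", "max_score")]
  long <- do.call(rbind, lapply(strains, function(s)
    data.frame(strain = s, test_id = wide$test_id, category = wide$category,
               points = wide[[s]], max_score = wide$max_score,
               missing = is.na(wide[[s]]), stringsAsFactors = FALSE)))
  scores <- subscore_table(long, battery)
  totals <- c(A6 = 78.95, FZB42 = 67.75, DSM7 = 61.5, D747 = 65.25)
  sums <- vapply(strains, function(s) {
    sub <- scores[scores$strain == s, ]
    sum(ifelse(sub$missing, 0, sub$points))
  }, numeric(1))
  if (any(abs(sums - totals) > 1e-9))
    stop("packaged score table is corrupt: column sums do not match totals",
         call. = FALSE)
  if (abs(sum(battery$max_score) - 100) > 1e-9)
    stop("packaged score table is corrupt: maxima do not sum to 100",
         call. = FALSE)
  list(battery = battery, scores = scores, totals = totals, strains = strains)
}

#' Tier profile of a reference strain
#'
#' Converts one column of the packaged score table into an effect-tier
#' profile (points / max per test) for the synthetic generator, so a panel
#' can be engineered whose scoring reproduces that strain's column.
#'
#' @param strain one of `"A6"`, `"FZB42"`, `"DSM7"`, `"D747"`.
#' @return named numeric vector of fractions in `[0, 1]` (`NA` for the
#'   missing cell), one per test id.
#' @export
table3_profile <- function(strain = c("A6", "FZB42", "DSM7", "D747")) {
  strain <- match.arg(strain)
  fx <- table3_fixture()
  sub <- fx$scores[fx$scores$strain == strain, ]
  stats::setNames(ifelse(sub$missing, NA_real_, sub$points / sub$max_score),
                  sub$test_id)
}
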