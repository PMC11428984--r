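#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] returning the p-value;
#' samples with p > 0.05 are treated as compatible with normality by the
#' grading pipeline.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return the Shapiro-Wilk p-value.
#' @export
check_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("normality statistic undefined for a constant sample", call. = FALSE)
  stats::shapiro.test(values)$p.value
}

# One Bonferroni outlier step on a fitted lm: index of the most extreme
# studentized residual if its Bonferroni-adjusted two-sided p < alpha,
# otherwise 0. Mirrors the classical outlier test on model residuals.
bonferroni_step <- function(fit, alpha) {
  t <- stats::rstudent(fit)
  t[!is.finite(t)] <- 0
  df <- stats::df.residual(fit) - 1L
  if (df < 1) return(0L)
  i <- which.max(abs(t))
  p <- min(1, length(t) * 2 * stats::pt(-abs(t[i]), df))
  if (p < alpha) i else 0L
}

#' Iterative Bonferroni outlier screening
#'
#' Repeatedly flags the observation with the largest absolute studentized
#' residual whose Bonferroni-adjusted p-value falls below `alpha` (one flag
#' per iteration), refitting after each removal, and stops when no
#' observation is significant. With no grouping the model is an intercept-only
#' fit; with `group` given, residuals are screened against the one-way group
#' model, so screening operates on model residuals rather than per group.
#'
#' @param values numeric sample.
#' @param alpha significance level for the Bonferroni-adjusted test.
#' @param group optional factor of the same length as `values`.
#' @return list with `values` (kept observations), `flagged` (integer
#'   indices into the original input) and, when grouped, `group` (kept
#'   grouping values).
#' @export
remove_outliers <- function(values, alpha = 0.05, group = NULL) {
  n <- length(values)
  if (n < 4) {
    warning("fewer than 4 observations; outlier screening skipped", call. = FALSE)
    return(list(values = values, flagged = integer(), group = group))
  }
  keep <- seq_len(n)
  flagged <- integer()
  repeat {
    if (length(keep) < 4) break
    v <- values[keep]
    if (stats::sd(v) == 0) break
    fit <- if (is.null(group)) stats::lm(v ~ 1)
           else {
             g <- factor(group[keep])
             if (nlevels(g) < 2) stats::lm(v ~ 1) else stats::lm(v ~ g)
           }
    # residual scatter at rounding level means nothing left to screen
    if (sqrt(mean(stats::residuals(fit)^2)) <= 1e-10 * max(abs(v), 1)) break
    i <- bonferroni_step(fit, alpha)
    if (i == 0L) break
    flagged <- c(flagged, keep[i])
    keep <- keep[-i]
  }
  list(values = values[keep], flagged = sort(flagged),
       group = if (is.null(group)) NULL else group[keep])
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way F-test via [stats::oneway.test()] with equal variances
#' assumed. Degenerate inputs (zero within-group variance) are resolved by
#' the sums of squares: F is 0 with p = 1 when all group means coincide, and
#' infinite with p = 0 otherwise.
#'
#' @param groups list of numeric samples, each of length >= 2.
#' @return list with `statistic` (F), `p.value`, and `df` (numerator,
#'   denominator).
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(groups)
  N <- sum(lengths(groups))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  df <- c(k - 1L, N - k)
  if (ssw <= .Machine$double.eps * max(ssb, 1)) {
    if (ssb <= .Machine$double.eps * max(abs(gm), 1))
      return(list(statistic = 0, p.value = 1, df = df))
    return(list(statistic = Inf, p.value = 0, df = df))
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = ft$p.value, df = df)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons of group means using the studentized range
#' distribution with the pooled within-group variance; unbalanced designs
#' use the Tukey-Kramer standard error. Zero pooled variance is resolved by
#' convention: p = 0 for pairs with unequal means, p = 1 for equal means.
#'
#' @param groups named list of numeric samples, each of length >= 2.
#' @param alpha significance level (carried in the result for letter
#'   grouping; the p-values themselves do not depend on it).
#' @return symmetric matrix of Tukey-adjusted p-values with unit diagonal,
#'   dimnames taken from `groups`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(groups)
  ids <- names(groups)
  if (is.null(ids)) ids <- paste0("g", seq_len(k))
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  df <- sum(n) - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  p <- matrix(1, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- abs(m[i] - m[j])
    pij <- if (s2 <= 0) {
      if (d <= .Machine$double.eps * max(abs(m[i]), abs(m[j]), 1)) 1 else 0
    } else {
      se <- sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
      stats::ptukey(d / se, k, df, lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pij
  }
  p
}

# Letter labels a, b, ..., z, aa, ab, ... for an arbitrary number of columns.
letter_labels <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
}

#' Compact-letter display
#'
#' Assigns letters to groups so that two groups share at least one letter
#' exactly when their adjusted pairwise p-value is >= `alpha`
#' (insert-and-absorb construction: start from one letter covering all
#' groups; for each significant pair, split every letter containing both and
#' absorb redundant letters).
#'
#' @param pairwise_p symmetric matrix of adjusted p-values with unit
#'   diagonal (e.g. from [tukey_hsd()]).
#' @param alpha significance level.
#' @return character vector of letter strings, one per group, named by the
#'   matrix dimnames.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05) {
  k <- nrow(pairwise_p)
  if (k == 0) return(character())
  if (!isTRUE(all.equal(pairwise_p, t(pairwise_p))))
    stop("pairwise p-value matrix must be symmetric", call. = FALSE)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(max(k - 1, 0))) for (j in seq_len(k)[-seq_len(i)]) {
    if (pairwise_p[i, j] >= alpha) next
    hit <- vapply(cols, function(cl) cl[i] && cl[j], logical(1))
    if (!any(hit)) next
    new_cols <- list()
    for (idx in seq_along(cols)) {
      cl <- cols[[idx]]
      if (!hit[idx]) { new_cols[[length(new_cols) + 1L]] <- cl; next }
      a <- cl; a[i] <- FALSE
      b <- cl; b[j] <- FALSE
      new_cols[[length(new_cols) + 1L]] <- a
      new_cols[[length(new_cols) + 1L]] <- b
    }
    # absorb: drop any column whose member set is contained in another's
    keep <- rep(TRUE, length(new_cols))
    for (a_i in seq_along(new_cols)) for (b_i in seq_along(new_cols)) {
      if (a_i == b_i || !keep[a_i] || !keep[b_i]) next
      a <- new_cols[[a_i]]; b <- new_cols[[b_i]]
      if (all(!a | b) && (any(b & !a) || a_i > b_i)) keep[a_i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  cols <- cols[order(vapply(cols, which.max, integer(1)))]  # figure reading order
  labs <- letter_labels(length(cols))
  out <- vapply(seq_len(k), function(g)
    paste(labs[vapply(cols, `[`, logical(1), g)], collapse = ""), character(1))
  names(out) <- rownames(pairwise_p)
  out
}

#' Full grading pipeline for one set of groups
#'
#' Runs the statistical grading used throughout the package on a set of
#' replicate groups: iterative Bonferroni outlier screening on the one-way
#' model residuals, Shapiro-Wilk normality check of the screened residuals
#' (recorded, never fatal), one-way ANOVA, Tukey HSD pairwise comparisons
#' and a compact-letter display.
#'
#' @param groups named list of numeric replicate samples.
#' @param alpha significance level (default 0.05).
#' @param screen_outliers logical; run the Bonferroni screen first.
#' @return object of class `group_comparison`: list with `group_ids`,
#'   `means`, `n`, `anova_F`, `anova_p`, `pairwise_p`, `letters`,
#'   `normality_p` (NA when undefined), `outliers_removed` (per-group
#'   counts) and `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05, screen_outliers = TRUE) {
  ids <- names(groups)
  if (is.null(ids)) {
    ids <- paste0("g", seq_along(groups))
    names(groups) <- ids
  }
  removed <- stats::setNames(integer(length(groups)), ids)
  if (screen_outliers) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(ids, lengths(groups))
    if (length(x) >= 4 && stats::sd(x) > 0) {
      scr <- remove_outliers(x, alpha = alpha, group = g)
      if (length(scr$flagged)) {
        dropped <- table(g[scr$flagged])
        removed[names(dropped)] <- as.integer(dropped)
        groups <- split(scr$values, factor(scr$group, levels = ids))
      }
    }
  }
  if (any(lengths(groups) < 2))
    stop("a group fell below 2 replicates", call. = FALSE)
  res <- unlist(lapply(groups, function(g) g - mean(g)), use.names = FALSE)
  norm_p <- tryCatch(check_normality(res), error = function(e) NA_real_)
  an <- oneway_anova(groups)
  p <- tukey_hsd(groups, alpha = alpha)
  structure(list(
    group_ids = ids,
    means = vapply(groups, mean, numeric(1)),
    n = lengths(groups),
    anova_F = an$statistic, anova_p = an$p.value,
    pairwise_p = p,
    letters = compact_letters(p, alpha = alpha),
    normality_p = norm_p,
    outliers_removed = removed,
    alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%d groups): F = %.4g, p = %.4g\n",
              length(x$group_ids), x$anova_F, x$anova_p))
  tab <- data.frame(group = x$group_ids, n = as.integer(x$n),
                    mean = signif(x$means, 5), letters = x$letters,
                    row.names = NULL)
  print(tab, row.names = FALSE)
  if (!is.na(x$normality_p) && x$normality_p <= 0.05)
    cat("note: residual normality check p =", signif(x$normality_p, 3), "\n")
  invisible(x)
}
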