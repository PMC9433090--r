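#' Two-sample t-test
#'
#' Two-tailed two-sample t-test, Welch (unequal variance) by default. The
#' pooled-variance variant is available through `equal_var = TRUE`. When both
#' samples are constant the test statistic is undefined; identical constants
#' return `p = 1` (no evidence of a difference), differing constants return
#' `p = 0`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param equal_var Pool variances (classical t) instead of Welch.
#' @param n_comparisons Bonferroni family size used for `p_adj`.
#' @return A one-row tibble with `statistic`, `df`, `p_raw`, `p_adj`,
#'   `n_comparisons` and `method`.
#' @examples
#' two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
two_sample_t <- function(a, b, equal_var = FALSE, n_comparisons = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("two_sample_t() needs at least 2 observations per group", call. = FALSE)
  }
  method <- if (equal_var) "t-test (pooled)" else "t-test (Welch)"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    statistic <- if (same) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (same) 1 else 0
    return(tibble::tibble(
      statistic = statistic, df = NA_real_, p_raw = p,
      p_adj = min(1, p * n_comparisons),
      n_comparisons = as.integer(n_comparisons), method = method
    ))
  }
  fit <- stats::t.test(a, b, var.equal = equal_var, alternative = "two.sided")
  tibble::tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_raw = fit$p.value, p_adj = min(1, fit$p.value * n_comparisons),
    n_comparisons = as.integer(n_comparisons), method = method
  )
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each p-value, with `m` the family size (the length of
#' the vector unless overridden).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p * m)
}

as_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("2x2 table must hold non-negative counts", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

#' Fisher exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] with defined behaviour for
#' degenerate tables: a zero row or column margin carries no information, so
#' `p = 1` is returned with a warning.
#'
#' @param tab 2x2 count matrix `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (on the odds
#'   ratio of the first cell).
#' @return List with `odds_ratio` (conditional MLE), `p` and the `table`.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); returning p = 1", call. = FALSE)
    return(list(odds_ratio = NA_real_, p = 1, table = tab, method = "fisher"))
  }
  fit <- stats::fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(fit$estimate), p = fit$p.value, table = tab,
       method = "fisher")
}

#' Chi-squared test on a 2x2 table with small-count fallback
#'
#' Pearson chi-squared test without Yates continuity correction by default
#' (`correct = TRUE` enables it). When any expected cell count falls below
#' `min_expected` the asymptotic approximation is unreliable and the test
#' falls back to the (two-sided) Fisher exact test; set
#' `fallback_fisher = FALSE` to disable. Zero margins give `p = 1` with a
#' warning.
#'
#' @param tab 2x2 count matrix.
#' @param correct Apply Yates continuity correction.
#' @param fallback_fisher Use Fisher exact test when expected counts are small.
#' @param min_expected Expected-count threshold for the fallback (default 5).
#' @return List with `statistic` (NA when the fallback fired), `p`, `method`
#'   and the `table`.
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE, fallback_fisher = TRUE,
                            min_expected = 5) {
  tab <- as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); returning p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p = 1, method = "degenerate", table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (fallback_fisher && any(expected < min_expected)) {
    fit <- stats::fisher.test(tab, alternative = "two.sided")
    return(list(statistic = NA_real_, p = fit$p.value,
                method = "fisher (expected < 5)", table = tab))
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(fit$statistic), p = fit$p.value,
       method = if (correct) "chi-squared (Yates)" else "chi-squared",
       table = tab)
}

#' Two-way fixed-effects ANOVA
#'
#' Standard two-way ANOVA decomposition with interaction, fitted with
#' [stats::aov()] on one response value per (subject, level) combination.
#' Intended for per-animal bin means: `response ~ factor_a * factor_b`.
#'
#' @param data Data frame holding the response and both factors.
#' @param response,factor_a,factor_b Column names (strings).
#' @return Tibble with one row per term (`factor_a`, `factor_b`, interaction):
#'   `term`, `df`, `sum_sq`, `statistic`, `p`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  data <- as.data.frame(data)
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("column '", col, "' not found", call. = FALSE)
  }
  fa <- factor(data[[factor_a]]); fb <- factor(data[[factor_b]])
  cell_n <- table(fa, fb)
  if (any(cell_n == 0)) {
    stop("empty cell in the ", factor_a, " x ", factor_b, " design", call. = FALSE)
  }
  df <- data.frame(y = as.numeric(data[[response]]), a = fa, b = fb)
  fit <- stats::aov(y ~ a * b, data = df)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b))[seq_len(sum(keep))],
    df = sm$Df[keep],
    sum_sq = sm$`Sum Sq`[keep],
    statistic = sm$`F value`[keep],
    p = sm$`Pr(>F)`[keep]
  )
}
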