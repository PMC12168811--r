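#' Normality-gated two-group comparison
#'
#' Each group is tested for normality (Shapiro-Wilk at
#' `normality_alpha`); when both pass, a two-tailed unpaired t test is used,
#' otherwise a two-tailed Mann-Whitney test. The small-sample Mann-Whitney
#' branch uses the exact U distribution when no ties are present and the
#' tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors, each with at least 3 values.
#' @param normality_alpha Gate level for the Shapiro-Wilk tests (default
#'   0.05).
#' @param var_equal Pooled-variance t test (default `TRUE`, the classical
#'   independent-samples test).
#' @param parameter Optional label for the compared parameter.
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @export
auto_compare <- function(group_a, group_b, normality_alpha = 0.05,
                         var_equal = TRUE, parameter = NULL) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort("Each group needs at least 3 values.")
  }
  sw_a <- stats::shapiro.test(group_a)$p.value
  sw_b <- stats::shapiro.test(group_b)$p.value
  normal <- sw_a >= normality_alpha && sw_b >= normality_alpha
  if (normal) {
    ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
    test_used <- "t_unpaired"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b))
    test_used <- "mann_whitney"
  }
  structure(
    list(
      parameter = parameter %||% NA_character_,
      test_used = test_used,
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      n_a = length(group_a), n_b = length(group_b),
      mean_a = mean(group_a), mean_b = mean(group_b),
      median_a = stats::median(group_a), median_b = stats::median(group_b),
      shapiro_p_a = sw_a, shapiro_p_b = sw_b,
      normality_alpha = normality_alpha,
      group_a = group_a, group_b = group_b
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", if (!is.na(x$parameter)) x$parameter else "", "\n",
      "  test: ", x$test_used, " (Shapiro p = ",
      signif(x$shapiro_p_a, 3), " / ", signif(x$shapiro_p_b, 3), ")\n",
      "  statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 4),
      ", n = ", x$n_a, "/", x$n_b, "\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's probability (with a relative slack of 1e-7 for floating-point
#' ties, the conventional rule).
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return The two-sided p value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate table: all row and column margins must be positive.")
  }
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni family ledger
#'
#' For a family of `m` parameter-level tests at family-wise level
#' `family_alpha`, the per-test threshold is `family_alpha / m`. The
#' displayed threshold is truncated to three decimal places (the convention
#' used when reporting such ledgers), while significance flags always use
#' the untruncated threshold.
#'
#' @param p_values Numeric vector of per-parameter p values, optionally
#'   named.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return An object of class `family_ledger`: a tibble (`parameter`,
#'   `p_value`, `significant`) with attributes `m`, `family_alpha`,
#'   `per_test_threshold`, `display_threshold`.
#' @export
bonferroni_ledger <- function(p_values, family_alpha = 0.05) {
  m <- length(p_values)
  if (m == 0L) abort("Empty family: at least one p value is required.")
  thr <- family_alpha / m
  out <- tibble(
    parameter = names(p_values) %||% paste0("param_", seq_len(m)),
    p_value = as.numeric(p_values),
    significant = as.numeric(p_values) < thr
  )
  structure(out, m = m, family_alpha = family_alpha,
            per_test_threshold = thr,
            display_threshold = floor(thr * 1000) / 1000,
            class = c("family_ledger", class(out)))
}

#' @export
print.family_ledger <- function(x, ...) {
  cat("<family_ledger> m = ", attr(x, "m"),
      ", family alpha = ", attr(x, "family_alpha"),
      ", per-test threshold = ", signif(attr(x, "per_test_threshold"), 5),
      " (displayed ", attr(x, "display_threshold"), ")\n", sep = "")
  NextMethod()
}

#' Integer percentage of a count
#'
#' `100 * k / n` rounded to the nearest integer percent, the convention used
#' when reporting study proportions.
#'
#' @param k,n Counts.
#' @return Integer percent.
#' @export
proportion_pct <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be positive.")
  as.integer(round(100 * k / n))
}
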