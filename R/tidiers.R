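#' Tidy a two-group comparison
#'
#' @param x A `group_comparison` from [auto_compare()].
#' @param ... Unused.
#' @return A one-row tibble with the test, statistic, p value and group
#'   summaries.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    parameter = x$parameter, test_used = x$test_used,
    statistic = x$statistic, p_value = x$p_value,
    n_a = x$n_a, n_b = x$n_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    median_a = x$median_a, median_b = x$median_b
  )
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    test_used = x$test_used, statistic = x$statistic, p_value = x$p_value,
    shapiro_p_a = x$shapiro_p_a, shapiro_p_b = x$shapiro_p_b,
    normality_alpha = x$normality_alpha
  )
}

#' Tidy a Bonferroni family ledger
#'
#' @param x A `family_ledger` from [bonferroni_ledger()].
#' @param ... Unused.
#' @return The per-parameter tibble (`tidy`) or a one-row family summary
#'   (`glance`).
#' @export
tidy.family_ledger <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.family_ledger
#' @export
glance.family_ledger <- function(x, ...) {
  tibble(
    m = attr(x, "m"), family_alpha = attr(x, "family_alpha"),
    per_test_threshold = attr(x, "per_test_threshold"),
    display_threshold = attr(x, "display_threshold"),
    n_significant = sum(x$significant)
  )
}

#' Tidy a literature RMP synthesis
#'
#' @param x An `rmp_meta` from [literature_meta()].
#' @param ... Unused.
#' @return Per-study effects and bins (`tidy`) or the one-row pooled
#'   summary (`glance`).
#' @export
tidy.rmp_meta <- function(x, ...) {
  x$per_study
}

#' @rdname tidy.rmp_meta
#' @export
glance.rmp_meta <- function(x, ...) {
  tibble(
    n_studies = x$n_studies,
    mean_effect_mV = x$mean_effect_mV,
    mw_statistic = x$mw_statistic, mw_p = x$mw_p,
    paired_t_statistic = x$paired_t_statistic, paired_t_p = x$paired_t_p,
    n_negligible = as.integer(x$bin_counts[["negligible"]]),
    n_moderate = as.integer(x$bin_counts[["moderate"]]),
    n_large = as.integer(x$bin_counts[["large"]])
  )
}
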