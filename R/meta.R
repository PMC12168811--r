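#' Literature synthesis of resting membrane potential shifts
#'
#' Pools per-study control and inflamed resting membrane potentials
#' extracted from the literature. Each study's effect is
#' `rmp_infl_mV - rmp_ctrl_mV`; absolute effects are binned into
#' negligible (< 1.5 mV), moderate (1.5 to < 10 mV), and large (>= 10 mV)
#' shifts. Two group-level tests are reported side by side because they can
#' disagree: a Mann-Whitney test on the pooled control vs inflamed columns,
#' and a paired t test on the per-study pairs (equivalently, a one-sample t
#' test on the differences). Studies missing either value are dropped with a
#' warning.
#'
#' @param records Data frame with columns `study_id`, `rmp_ctrl_mV`,
#'   `rmp_infl_mV` (one row per study); further columns are carried through.
#' @param bin_edges_mV Lower edges of the moderate and large bins
#'   (default `c(1.5, 10)`).
#' @return An object of class `rmp_meta`: per-study tibble plus pooled test
#'   results. `tidy()` returns the per-study table, `glance()` the one-row
#'   summary.
#' @export
literature_meta <- function(records, bin_edges_mV = c(1.5, 10)) {
  stopifnot(all(c("study_id", "rmp_ctrl_mV", "rmp_infl_mV") %in% names(records)))
  records <- as_tibble(records)
  incomplete <- is.na(records$rmp_ctrl_mV) | is.na(records$rmp_infl_mV)
  if (any(incomplete)) {
    warn(paste0("Dropping ", sum(incomplete),
                " record(s) without both RMP values: ",
                paste(records$study_id[incomplete], collapse = ", ")))
    records <- records[!incomplete, ]
  }
  if (nrow(records) < 2L) {
    abort("At least 2 complete records are required for the pooled tests.")
  }
  per_study <- records %>%
    mutate(
      effect_mV = .data$rmp_infl_mV - .data$rmp_ctrl_mV,
      effect_bin = cut(abs(.data$effect_mV),
                       breaks = c(0, bin_edges_mV, Inf),
                       labels = c("negligible", "moderate", "large"),
                       right = FALSE, include.lowest = TRUE)
    )
  mw <- suppressWarnings(
    stats::wilcox.test(per_study$rmp_infl_mV, per_study$rmp_ctrl_mV)
  )
  paired <- tryCatch(
    stats::t.test(per_study$rmp_infl_mV, per_study$rmp_ctrl_mV, paired = TRUE),
    error = function(e) NULL  # zero-variance differences: p undefined
  )
  structure(
    list(
      per_study = per_study,
      n_studies = nrow(per_study),
      bin_counts = table(per_study$effect_bin),
      mw_statistic = unname(mw$statistic),
      mw_p = mw$p.value,
      paired_t_statistic = if (is.null(paired)) NA_real_ else unname(paired$statistic),
      paired_t_p = if (is.null(paired)) NA_real_ else paired$p.value,
      mean_effect_mV = mean(per_study$effect_mV)
    ),
    class = "rmp_meta"
  )
}

#' @export
print.rmp_meta <- function(x, ...) {
  cat("<rmp_meta> ", x$n_studies, " studies, mean shift ",
      signif(x$mean_effect_mV, 3), " mV\n",
      "  bins: ", paste(names(x$bin_counts), as.integer(x$bin_counts),
                        sep = "=", collapse = ", "), "\n",
      "  pooled Mann-Whitney p = ", signif(x$mw_p, 4),
      " | paired t p = ", signif(x$paired_t_p, 4), "\n", sep = "")
  invisible(x)
}

#' Read a literature-extraction table
#'
#' @param path CSV with at least `study_id`, `rmp_ctrl_mV`, `rmp_infl_mV`.
#' @return A tibble.
#' @export
read_extraction_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
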