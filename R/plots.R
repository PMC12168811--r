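#' Plot dF/F traces with epoch shading
#'
#' @param traces Long trace table (`roi_id`, `frame`, `raw_f`).
#' @param timeline An `acq_timeline`.
#' @param calls Optional per-ROI calls from [classify_cells()]; traces are
#'   then coloured by call.
#' @param n_max Maximum number of ROIs drawn (default 20).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, timeline, calls = NULL, n_max = 20L) {
  ids <- head(unique(traces$roi_id), n_max)
  df <- traces %>%
    filter(.data$roi_id %in% ids) %>%
    group_by(.data$roi_id) %>%
    mutate(dff = compute_dff(.data$raw_f, timeline)$dff) %>%
    ungroup() %>%
    mutate(time_s = (.data$frame - 1L) * timeline$frame_period_s)
  if (!is.null(calls)) {
    df <- left_join(df,
                    calls %>%
                      mutate(call = if_else(.data$responder, "responder",
                                            if_else(.data$live, "non-responder",
                                                    "dead"))) %>%
                      select("roi_id", "call"),
                    by = "roi_id")
  } else {
    df$call <- "trace"
  }
  fp <- timeline$frame_period_s
  epochs <- tibble(
    epoch = c("drug", "KCl"),
    from = c(timeline$compound_frame - 1L, timeline$kcl_window[1] - 1L) * fp,
    to = c(timeline$wash_window[1] - 1L, timeline$kcl_window[2]) * fp
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      data = epochs,
      ggplot2::aes(xmin = .data$from, xmax = .data$to, ymin = -Inf, ymax = Inf),
      fill = c("grey85", "grey70"), alpha = 0.5
    ) +
    ggplot2::geom_line(
      ggplot2::aes(.data$time_s, .data$dff,
                   group = .data$roi_id, colour = .data$call),
      linewidth = 0.3
    ) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an f-I curve
#'
#' @param fi Tibble `amplitude_pA`, `n_aps` (from [count_step_aps()]).
#' @return A ggplot object.
#' @export
plot_fi <- function(fi) {
  ggplot2::ggplot(fi, ggplot2::aes(.data$amplitude_pA, .data$n_aps)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "injected current (pA)", y = "APs per step") +
    ggplot2::theme_minimal()
}

#' Plot sweeps of a current-clamp recording
#'
#' @param recording A [sweep_recording()].
#' @param amplitudes Subset of amplitudes to draw (default: every fourth).
#' @return A ggplot object.
#' @export
plot_sweeps <- function(recording, amplitudes = NULL) {
  amps <- amplitudes %||%
    recording$amplitudes_pA[seq(1, length(recording$amplitudes_pA), by = 4)]
  sel <- which(recording$amplitudes_pA %in% amps)
  t_s <- seq_len(nrow(recording$sweeps)) / recording$sampling_rate_Hz
  df <- purrr::map_dfr(sel, function(s) {
    tibble(time_s = t_s, vm_mV = recording$sweeps[, s],
           amplitude_pA = recording$amplitudes_pA[s])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$vm_mV,
                                   group = .data$amplitude_pA,
                                   colour = .data$amplitude_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "Vm (mV)", colour = "I (pA)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rmp_meta <- function(object, ...) {
  df <- object$per_study %>%
    tidyr::pivot_longer(c("rmp_ctrl_mV", "rmp_infl_mV"),
                        names_to = "condition", values_to = "rmp_mV") %>%
    mutate(condition = if_else(.data$condition == "rmp_ctrl_mV",
                               "control", "inflamed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$rmp_mV)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$study_id,
                                    colour = .data$effect_bin)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$effect_bin)) +
    ggplot2::scale_colour_manual(values = c(negligible = "black",
                                            moderate = "steelblue",
                                            large = "darkorange")) +
    ggplot2::labs(x = NULL, y = "resting membrane potential (mV)",
                  colour = "effect size") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.family_ledger <- function(object, ...) {
  df <- as_tibble(object)
  thr <- attr(object, "per_test_threshold")
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$parameter, .data$p_value),
                                   .data$p_value, colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "p value (log scale)",
                  colour = "below family threshold") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble(
    group = c(rep("A", object$n_a), rep("B", object$n_b)),
    value = c(object$group_a, object$group_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.3, linewidth = 0.3) +
    ggplot2::labs(
      subtitle = paste0(object$test_used, ", p = ", signif(object$p_value, 3)),
      x = NULL, y = object$parameter %||% "value"
    ) +
    ggplot2::theme_minimal()
}
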