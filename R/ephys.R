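#' Current-clamp sweep recording
#'
#' Container for a family of membrane-potential sweeps recorded at ascending
#' step amplitudes, with an optional gap-free segment for spontaneous
#' activity. Potentials are in mV; the liquid junction potential is stored
#' but not applied until [correct_ljp()] is called.
#'
#' @param sweeps Numeric matrix, one column per sweep (samples x sweeps).
#' @param amplitudes_pA Ascending injected amplitudes, one per column.
#' @param sampling_rate_Hz Sampling rate (> 0).
#' @param step_start_s,step_duration_s Stimulus timing in seconds.
#' @param ljp_mV Liquid junction potential (default -14).
#' @param holding_mode `"resting"` or `"held_minus75"`.
#' @param gapfree Optional numeric vector, a gap-free recording at rest.
#' @return An object of class `sweep_recording`.
#' @export
sweep_recording <- function(sweeps, amplitudes_pA, sampling_rate_Hz,
                            step_start_s, step_duration_s, ljp_mV = -14,
                            holding_mode = "resting", gapfree = NULL) {
  sweeps <- as.matrix(sweeps)
  if (length(amplitudes_pA) != ncol(sweeps)) {
    abort("One amplitude per sweep column is required.")
  }
  if (any(diff(amplitudes_pA) <= 0)) abort("Amplitudes must be strictly ascending.")
  if (sampling_rate_Hz <= 0) abort("`sampling_rate_Hz` must be > 0.")
  structure(
    list(sweeps = sweeps, amplitudes_pA = as.numeric(amplitudes_pA),
         sampling_rate_Hz = sampling_rate_Hz,
         step_start_s = step_start_s, step_duration_s = step_duration_s,
         ljp_mV = ljp_mV, holding_mode = holding_mode,
         gapfree = gapfree, ljp_applied = FALSE),
    class = "sweep_recording"
  )
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat("<sweep_recording> ", ncol(x$sweeps), " sweeps x ", nrow(x$sweeps),
      " samples @ ", x$sampling_rate_Hz, " Hz (", x$holding_mode, ")\n",
      "  steps ", min(x$amplitudes_pA), "..", max(x$amplitudes_pA),
      " pA, LJP ", x$ljp_mV, " mV",
      if (x$ljp_applied) " (applied)" else " (not applied)",
      if (!is.null(x$gapfree)) {
        paste0(", gap-free ", round(length(x$gapfree) / x$sampling_rate_Hz, 1), " s")
      } else "", "\n", sep = "")
  invisible(x)
}

#' Apply the liquid junction potential correction offline
#'
#' Every recorded potential (sweeps and gap-free segment) is shifted by the
#' stored LJP: `corrected = recorded + ljp_mV` (default -14 mV). A state
#' flag guards idempotence; correcting twice raises an error and leaves the
#' recording unchanged.
#'
#' @param recording A [sweep_recording()].
#' @return The corrected recording.
#' @export
correct_ljp <- function(recording) {
  stopifnot(inherits(recording, "sweep_recording"))
  if (isTRUE(recording$ljp_applied)) {
    abort("LJP correction already applied; refusing to correct twice.")
  }
  recording$sweeps <- recording$sweeps + recording$ljp_mV
  if (!is.null(recording$gapfree)) {
    recording$gapfree <- recording$gapfree + recording$ljp_mV
  }
  recording$ljp_applied <- TRUE
  recording
}

#' Action-potential detection parameters
#'
#' @param dvdt_threshold_mV_per_ms Upstroke threshold on dV/dt (default 10).
#' @param min_interevent_ms Minimum separation between event onsets; later
#'   crossings within this window of an accepted onset are merged into the
#'   same event (default 2).
#' @param peak_search_ms Window after onset searched for the spike peak
#'   (default 5).
#' @return A list of class `ap_detection_params`.
#' @export
ap_detection_params <- function(dvdt_threshold_mV_per_ms = 10,
                                min_interevent_ms = 2, peak_search_ms = 5) {
  if (dvdt_threshold_mV_per_ms <= 0) abort("dV/dt threshold must be > 0.")
  structure(
    list(dvdt_threshold_mV_per_ms = dvdt_threshold_mV_per_ms,
         min_interevent_ms = min_interevent_ms,
         peak_search_ms = peak_search_ms),
    class = "ap_detection_params"
  )
}

#' Detect action potentials on one sweep
#'
#' An action potential is an upward crossing of the dV/dt threshold
#' (forward difference at the native sampling rate, in mV/ms). Crossings
#' closer than `min_interevent_ms` to the previous accepted onset are merged
#' into that event. Each event's peak is the Vm maximum within
#' `peak_search_ms` of onset.
#'
#' @param sweep Numeric vector of membrane potential (mV).
#' @param sampling_rate_Hz Sampling rate.
#' @param params An [ap_detection_params()].
#' @return Tibble with one row per event: `onset_idx`, `peak_idx`,
#'   `threshold_mV` (Vm at onset), `peak_mV`. Zero rows when nothing fires.
#' @export
detect_aps <- function(sweep, sampling_rate_Hz, params = ap_detection_params()) {
  n <- length(sweep)
  if (n < 2L) abort("Sweep must contain at least 2 samples.")
  dt_ms <- 1000 / sampling_rate_Hz
  dvdt <- diff(sweep) / dt_ms
  thr <- params$dvdt_threshold_mV_per_ms
  supra <- dvdt >= thr
  crossing <- supra & !c(FALSE, supra[-length(supra)])
  idx <- which(crossing)
  if (length(idx) == 0L) {
    return(tibble(onset_idx = integer(), peak_idx = integer(),
                  threshold_mV = numeric(), peak_mV = numeric()))
  }
  min_gap <- params$min_interevent_ms / dt_ms
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
  peak_n <- max(1L, round(params$peak_search_ms / dt_ms))
  peak_idx <- vapply(keep, function(o) {
    win <- seq.int(o, min(n, o + peak_n))
    win[which.max(sweep[win])]
  }, integer(1))
  tibble(
    onset_idx = as.integer(keep),
    peak_idx = peak_idx,
    threshold_mV = sweep[keep],
    peak_mV = sweep[peak_idx]
  )
}

#' Resting membrane potential of a sweep
#'
#' Mean membrane potential over the `window_s` seconds immediately preceding
#' the stimulus step.
#'
#' @param sweep Numeric vector (mV).
#' @param sampling_rate_Hz Sampling rate.
#' @param step_start_s Stimulus onset in seconds; at least `window_s` of
#'   pre-stimulus data must exist.
#' @param window_s Averaging window (default 0.2).
#' @return RMP in mV.
#' @export
measure_rmp <- function(sweep, sampling_rate_Hz, step_start_s, window_s = 0.2) {
  n_pre <- floor(step_start_s * sampling_rate_Hz)
  n_win <- round(window_s * sampling_rate_Hz)
  if (n_pre < n_win) {
    abort("Insufficient pre-stimulus data for the RMP window.")
  }
  mean(sweep[seq.int(n_pre - n_win + 1L, n_pre)])
}

# Internal: step window in sample indices for a recording.
.step_samples <- function(recording) {
  n_pre <- round(recording$step_start_s * recording$sampling_rate_Hz)
  n_step <- round(recording$step_duration_s * recording$sampling_rate_Hz)
  c(first = n_pre + 1L, last = n_pre + n_step)
}

#' Spike counts per sweep (f-I curve)
#'
#' Counts detected action potentials whose onset falls inside the stimulus
#' step window, for every sweep.
#'
#' @param recording A [sweep_recording()].
#' @param params An [ap_detection_params()].
#' @return Tibble `amplitude_pA`, `n_aps`.
#' @export
count_step_aps <- function(recording, params = ap_detection_params()) {
  win <- .step_samples(recording)
  n_aps <- vapply(seq_len(ncol(recording$sweeps)), function(s) {
    ev <- detect_aps(recording$sweeps[, s], recording$sampling_rate_Hz, params)
    sum(ev$onset_idx >= win["first"] & ev$onset_idx <= win["last"])
  }, integer(1))
  tibble(amplitude_pA = recording$amplitudes_pA, n_aps = n_aps)
}

#' Rheobase of a recording
#'
#' The minimum injected current amplitude whose step window contains at
#' least one detected action potential; `NA` when no sweep fires (which
#' feeds the exclusion rule).
#'
#' @param recording A [sweep_recording()] at resting mode.
#' @param params An [ap_detection_params()].
#' @return Amplitude in pA, or `NA_real_`.
#' @export
measure_rheobase <- function(recording, params = ap_detection_params()) {
  fi <- count_step_aps(recording, params)
  fired <- fi$amplitude_pA[fi$n_aps > 0]
  if (length(fired) == 0L) NA_real_ else min(fired)
}

# Internal: linearly interpolated time (in samples, fractional) at which the
# trace crosses `level`, scanning from `from` towards `to`.
.cross_time <- function(v, level, from, to) {
  step <- if (to >= from) 1L else -1L
  idx <- seq.int(from, to, by = step)
  for (k in idx[-1]) {
    prev <- k - step
    if ((v[prev] - level) * (v[k] - level) <= 0 && v[prev] != v[k]) {
      return(prev + step * (level - v[prev]) / (v[k] - v[prev]))
    }
  }
  NA_real_
}

#' Waveform features of the first action potential
#'
#' Measured on the first suprathreshold sweep of a recording made while
#' holding the cell at -75 mV. Threshold is Vm at the first dV/dt crossing;
#' peak amplitude is measured from the -75 mV holding level to the peak;
#' half-width is the interpolated duration at half peak amplitude; the fast
#' afterhyperpolarisation is the Vm minimum between the first peak and the
#' next event onset (or step end); the medium afterhyperpolarisation is the
#' Vm minimum in a 200 ms window after step offset; time to peak runs from
#' stimulus onset to the first peak.
#'
#' @param recording A [sweep_recording()] (held mode).
#' @param params An [ap_detection_params()].
#' @param ref_mV Reference potential for the amplitude measurement. The
#'   default (`NULL`) uses the measured pre-stimulus holding level of the
#'   analysed sweep — nominally -75 mV in the held protocol — which keeps
#'   amplitude and half-width invariant under the LJP shift; pass a number
#'   to fix the reference instead.
#' @param mahp_window_s Post-stimulus window for the medium AHP (default 0.2).
#' @return One-row tibble: `sweep_amplitude_pA`, `threshold_mV`,
#'   `peak_amplitude_mV`, `time_to_peak_ms`, `half_width_ms`, `fahp_mV`,
#'   `mahp_mV`.
#' @export
waveform_features <- function(recording, params = ap_detection_params(),
                              ref_mV = NULL, mahp_window_s = 0.2) {
  win <- .step_samples(recording)
  sr <- recording$sampling_rate_Hz
  for (s in seq_len(ncol(recording$sweeps))) {
    v <- recording$sweeps[, s]
    ref <- ref_mV %||% measure_rmp(v, sr, recording$step_start_s)
    ev <- detect_aps(v, sr, params)
    ev <- ev[ev$onset_idx >= win["first"] & ev$onset_idx <= win["last"], ]
    if (nrow(ev) == 0L) next
    onset <- ev$onset_idx[1]
    peak_idx <- ev$peak_idx[1]
    peak <- ev$peak_mV[1]
    amp <- peak - ref
    half_level <- ref + amp / 2
    fall_stop <- if (nrow(ev) > 1L) ev$onset_idx[2] else win["last"]
    t_rise <- .cross_time(v, half_level, peak_idx, onset)
    t_fall <- .cross_time(v, half_level, peak_idx, fall_stop)
    half_width <- if (is.na(t_rise) || is.na(t_fall)) NA_real_ else {
      (t_fall - t_rise) / sr * 1000
    }
    fahp_win <- seq.int(peak_idx + 1L, max(peak_idx + 1L, fall_stop))
    mahp_win <- seq.int(win["last"] + 1L,
                        min(nrow(recording$sweeps),
                            win["last"] + round(mahp_window_s * sr)))
    return(tibble(
      sweep_amplitude_pA = recording$amplitudes_pA[s],
      threshold_mV = ev$threshold_mV[1],
      peak_amplitude_mV = amp,
      time_to_peak_ms = (peak_idx - win[["first"]] + 1L) / sr * 1000,
      half_width_ms = half_width,
      fahp_mV = min(v[fahp_win]),
      mahp_mV = min(v[mahp_win])
    ))
  }
  abort("No action potential on any sweep: waveform features are undefined.")
}

#' Firing classification of a recording
#'
#' @param recording A [sweep_recording()]; the gap-free segment (if present)
#'   feeds the spontaneous-activity call.
#' @param params An [ap_detection_params()].
#' @return One-row tibble: `spontaneous` (`NA` when no gap-free segment is
#'   present), `n_spontaneous_aps`, `firing_pattern` (`"multiple"` if any
#'   sweep holds >= 2 APs, `"single"` if the maximum is 1, `"none"`
#'   otherwise), `max_aps`, and the f-I counts as a list column `fi`.
#' @export
classify_firing <- function(recording, params = ap_detection_params()) {
  fi <- count_step_aps(recording, params)
  max_aps <- max(fi$n_aps)
  pattern <- if (max_aps >= 2L) "multiple" else if (max_aps == 1L) "single" else "none"
  if (is.null(recording$gapfree)) {
    spont <- NA
    n_spont <- NA_integer_
  } else {
    ev <- detect_aps(recording$gapfree, recording$sampling_rate_Hz, params)
    n_spont <- nrow(ev)
    spont <- n_spont >= 1L
  }
  tibble(
    spontaneous = spont, n_spontaneous_aps = n_spont,
    firing_pattern = pattern, max_aps = as.integer(max_aps),
    fi = list(fi)
  )
}

#' Apply the study's exclusion rules to a cell profile
#'
#' A cell is excluded when it never fired an action potential upon current
#' injection (no rheobase) or when its resting membrane potential lies above
#' -40 mV.
#'
#' @param profile One-row tibble or list with `rmp_mV` and `rheobase_pA`.
#' @param rmp_cutoff_mV Exclusion cutoff (default -40).
#' @return One-row tibble: `excluded`, `reason` (`NA` when included).
#' @export
apply_exclusions <- function(profile, rmp_cutoff_mV = -40) {
  non_firing <- is.na(profile$rheobase_pA)
  depol <- !is.na(profile$rmp_mV) && profile$rmp_mV > rmp_cutoff_mV
  reason <- if (non_firing && depol) {
    "non-firing; depolarised RMP"
  } else if (non_firing) {
    "non-firing"
  } else if (depol) {
    "depolarised RMP"
  } else {
    NA_character_
  }
  tibble(excluded = non_firing || depol, reason = reason)
}

#' Full per-cell feature battery
#'
#' Combines resting membrane potential (first sweep of the resting-mode
#' recording), rheobase and firing classification (resting mode), waveform
#' features (held-at--75 recording, when supplied), and the exclusion rules
#' into one feature row per cell.
#'
#' @param recording A resting-mode [sweep_recording()].
#' @param held_recording Optional held-mode recording for waveform features.
#' @param params An [ap_detection_params()].
#' @return One-row tibble with `rmp_mV`, `rheobase_pA`, firing columns,
#'   waveform columns (`NA` when unavailable), `excluded`, `reason`.
#' @export
ephys_features <- function(recording, held_recording = NULL,
                           params = ap_detection_params()) {
  rmp <- measure_rmp(recording$sweeps[, 1], recording$sampling_rate_Hz,
                     recording$step_start_s)
  rheo <- measure_rheobase(recording, params)
  firing <- classify_firing(recording, params)
  wf <- if (!is.null(held_recording)) {
    tryCatch(waveform_features(held_recording, params),
             error = function(e) NULL)
  } else NULL
  if (is.null(wf)) {
    wf <- tibble(sweep_amplitude_pA = NA_real_, threshold_mV = NA_real_,
                 peak_amplitude_mV = NA_real_, time_to_peak_ms = NA_real_,
                 half_width_ms = NA_real_, fahp_mV = NA_real_, mahp_mV = NA_real_)
  }
  excl <- apply_exclusions(list(rmp_mV = rmp, rheobase_pA = rheo))
  bind_cols(tibble(rmp_mV = rmp, rheobase_pA = rheo), firing, wf, excl)
}
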