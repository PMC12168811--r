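#' Current-step stimulation protocol
#'
#' Square current steps of fixed duration delivered at ascending amplitudes,
#' either from rest or while holding the cell near -75 mV.
#'
#' @param step_start_s Seconds of pre-stimulus recording (default 0.3; at
#'   least 0.2 s is required so the resting membrane potential window fits).
#' @param step_duration_s Step length in seconds (default 0.2).
#' @param amplitudes_pA Strictly ascending injected amplitudes (default -50
#'   to 850 pA in 25 pA increments).
#' @param tail_s Seconds recorded after step offset (default 0.3; at least
#'   0.2 s for the medium-afterhyperpolarisation window).
#' @param inter_sweep_rate_Hz Sweep repetition rate (default 0.5 Hz;
#'   metadata only).
#' @param holding_mode `"resting"` or `"held_minus75"`.
#' @return A list of class `sweep_protocol`.
#' @export
sweep_protocol <- function(step_start_s = 0.3, step_duration_s = 0.2,
                           amplitudes_pA = seq(-50, 850, by = 25),
                           tail_s = 0.3, inter_sweep_rate_Hz = 0.5,
                           holding_mode = c("resting", "held_minus75")) {
  holding_mode <- match.arg(holding_mode)
  if (any(diff(amplitudes_pA) <= 0)) abort("Amplitudes must be strictly ascending.")
  if (step_start_s <= 0 || step_duration_s <= 0 || tail_s < 0) {
    abort("Step timing must be positive.")
  }
  structure(
    list(step_start_s = step_start_s, step_duration_s = step_duration_s,
         amplitudes_pA = as.numeric(amplitudes_pA), tail_s = tail_s,
         inter_sweep_rate_Hz = inter_sweep_rate_Hz, holding_mode = holding_mode),
    class = "sweep_protocol"
  )
}

#' Configuration of the adaptive exponential integrate-and-fire neuron
#'
#' The membrane follows
#' `C dV/dt = -gL (V - EL) + gL dT exp((V - VT)/dT) - w + I` with adaptation
#' `tau_w dw/dt = a (V - EL) - w`; when V reaches the 0 mV cutoff a spike is
#' registered, V resets and w increments by b. Reset events are the
#' unambiguous ground truth for spike counts and rheobase.
#'
#' @param leak_reversal_mV Leak reversal EL (resting potential at
#'   equilibrium), default -65.
#' @param leak_conductance_nS Leak conductance gL, default 10.
#' @param capacitance_pF Membrane capacitance C, default 100.
#' @param spike_threshold_mV Exponential threshold VT, default -50.
#' @param slope_factor_mV Slope factor dT, default 2.
#' @param a_nS,b_pA,tau_w_ms Adaptation parameters, defaults 2 nS / 40 pA /
#'   100 ms.
#' @param reset_mV Post-spike reset potential, default -65. The default
#'   reset depth and capacitance keep inter-spike intervals above the AP
#'   detector's 2 ms merge window and the passive charging slope of the
#'   largest protocol step below the 10 mV/ms upstroke threshold.
#' @param noise_sd_mV Per-sqrt(ms) membrane noise SD, default 0.
#' @param sampling_rate_Hz Fixed Euler step rate, >= 10000 (default 20000).
#' @param seed Integer seed.
#' @return A list of class `neuron_sim_config`.
#' @export
neuron_sim_config <- function(leak_reversal_mV = -65, leak_conductance_nS = 10,
                              capacitance_pF = 120, spike_threshold_mV = -50,
                              slope_factor_mV = 2, a_nS = 2, b_pA = 40,
                              tau_w_ms = 100, reset_mV = -65, noise_sd_mV = 0,
                              sampling_rate_Hz = 20000, seed = 1L) {
  if (sampling_rate_Hz < 10000) abort("`sampling_rate_Hz` must be >= 10000.")
  if (capacitance_pF <= 0) abort("`capacitance_pF` must be > 0.")
  if (noise_sd_mV < 0) abort("`noise_sd_mV` must be >= 0.")
  structure(
    list(leak_reversal_mV = leak_reversal_mV,
         leak_conductance_nS = leak_conductance_nS,
         capacitance_pF = capacitance_pF,
         spike_threshold_mV = spike_threshold_mV,
         slope_factor_mV = slope_factor_mV,
         a_nS = a_nS, b_pA = b_pA, tau_w_ms = tau_w_ms,
         reset_mV = reset_mV, noise_sd_mV = noise_sd_mV,
         sampling_rate_Hz = sampling_rate_Hz, seed = as.integer(seed)),
    class = "neuron_sim_config"
  )
}

# Internal: fixed-step Euler integration of the AdEx model for a set of
# injected-current traces (one column per sweep). Returns the membrane trace
# matrix, reset-event sample indices, and per-event initiation samples (the
# last upward 10 mV/ms crossing before each reset; with Euler stepping the
# forward difference of the trace equals the integrated dV/dt exactly, so
# this is the sample an upstroke detector sees).
.adex_integrate <- function(config, i_inj, v0, w0, noise) {
  n_steps <- nrow(i_inj)
  n_sw <- ncol(i_inj)
  dt <- 1000 / config$sampling_rate_Hz  # ms
  gl <- config$leak_conductance_nS
  el <- config$leak_reversal_mV
  cap <- config$capacitance_pF
  vt <- config$spike_threshold_mV
  delta <- config$slope_factor_mV
  v_cut <- 0
  v <- matrix(NA_real_, n_steps, n_sw)
  vv <- rep(v0, length.out = n_sw)
  ww <- rep(w0, length.out = n_sw)
  events <- vector("list", n_sw)
  onsets <- vector("list", n_sw)
  prev_dvdt <- rep(-Inf, n_sw)
  last_cross <- rep(NA_integer_, n_sw)
  for (k in seq_len(n_steps)) {
    ex <- gl * delta * exp(pmin((vv - vt) / delta, 20))
    dv <- (-gl * (vv - el) + ex - ww + i_inj[k, ]) / cap * dt
    if (!is.null(noise)) dv <- dv + noise[k, ] * sqrt(dt)
    dvdt <- dv / dt
    crossed <- dvdt >= 10 & prev_dvdt < 10
    if (any(crossed)) last_cross[crossed] <- k
    prev_dvdt <- dvdt
    dw <- (config$a_nS * (vv - el) - ww) / config$tau_w_ms * dt
    vv <- vv + dv
    ww <- ww + dw
    fired <- vv >= v_cut
    if (any(fired)) {
      for (s in which(fired)) {
        events[[s]] <- c(events[[s]], k)
        onsets[[s]] <- c(onsets[[s]], last_cross[s])
      }
      vv[fired] <- config$reset_mV
      ww[fired] <- ww[fired] + config$b_pA
      prev_dvdt[fired] <- Inf  # reset discontinuity is not an upstroke
    }
    if (any(!is.finite(vv)) || any(vv < -200)) {
      abort("Unstable integration: |Vm| exceeded 200 mV outside spike reset.")
    }
    v[k, ] <- vv
  }
  list(v = v, events = events, onsets = onsets)
}

# Internal: paste a stereotyped 2 ms triangular spike (1 ms rise to +30 mV,
# 1 ms fall) at each reset event so the dV/dt detector sees a realistic
# upstroke. The fall lands on the value the underlying simulation reached by
# the end of the paste window, keeping the rendered trace seamless (no step
# discontinuity for the detector to mistake for an upstroke). A rendering
# convention, not a biophysical waveform.
.render_spikes <- function(v, events, config) {
  n_steps <- nrow(v)
  half <- max(2L, round(0.001 * config$sampling_rate_Hz))
  for (s in seq_len(ncol(v))) {
    for (k in events[[s]]) {
      base <- if (k > 1L) v[k - 1L, s] else config$reset_mV
      dn_end <- min(k + 2L * half, n_steps)
      land <- v[dn_end, s]
      up <- seq.int(k, min(k + half, n_steps))
      v[up, s] <- base + (30 - base) * (up - k) / half
      dn <- seq.int(min(k + half, n_steps), dn_end)
      v[dn, s] <- 30 + (land - 30) * (dn - (k + half)) / half
    }
  }
  v
}

#' Simulate a current-clamp recording with ground truth
#'
#' Integrates the adaptive exponential integrate-and-fire model with a
#' fixed-step Euler scheme at the configured sampling rate, one sweep per
#' protocol amplitude. In `held_minus75` mode a steady holding current pins
#' the pre-stimulus potential at -75 mV. Ground truth (per-sweep spike
#' counts, rheobase) comes from the reset events of a noise-free
#' re-simulation; an optional gap-free segment at zero injected current is
#' produced for spontaneous-activity analysis.
#'
#' @param config A [neuron_sim_config()].
#' @param protocol A [sweep_protocol()].
#' @param gapfree_s Seconds of gap-free recording to simulate (0 for none).
#' @return A list: `recording` (a [sweep_recording()]) and `truth` (list with
#'   `rmp_mV`, `rheobase_pA` (`NA` if no sweep fires), `spikes_per_sweep`
#'   tibble, `n_spontaneous`).
#' @export
gen_current_clamp <- function(config, protocol = sweep_protocol(),
                              gapfree_s = 0) {
  stopifnot(inherits(config, "neuron_sim_config"),
            inherits(protocol, "sweep_protocol"))
  set.seed(config$seed)
  sr <- config$sampling_rate_Hz
  n_pre <- round(protocol$step_start_s * sr)
  n_step <- round(protocol$step_duration_s * sr)
  n_tail <- round(protocol$tail_s * sr)
  n_steps <- n_pre + n_step + n_tail
  amps <- protocol$amplitudes_pA
  n_sw <- length(amps)

  gl <- config$leak_conductance_nS
  el <- config$leak_reversal_mV
  if (protocol$holding_mode == "held_minus75") {
    vh <- -75
    i_hold <- gl * (vh - el) - gl * config$slope_factor_mV *
      exp((vh - config$spike_threshold_mV) / config$slope_factor_mV) +
      config$a_nS * (vh - el)
    v0 <- vh; w0 <- config$a_nS * (vh - el)
  } else {
    i_hold <- 0; v0 <- el; w0 <- 0
  }

  i_inj <- matrix(i_hold, n_steps, n_sw)
  step_idx <- seq.int(n_pre + 1L, n_pre + n_step)
  i_inj[step_idx, ] <- i_inj[step_idx, ] + matrix(amps, n_step, n_sw, byrow = TRUE)

  noisy <- config$noise_sd_mV > 0
  noise <- if (noisy) {
    matrix(rnorm(n_steps * n_sw, sd = config$noise_sd_mV), n_steps, n_sw)
  } else NULL
  sim <- .adex_integrate(config, i_inj, v0, w0, noise)
  truth_sim <- if (noisy) .adex_integrate(config, i_inj, v0, w0, NULL) else sim
  v <- .render_spikes(sim$v, sim$events, config)

  truth_counts <- vapply(truth_sim$onsets, function(o) {
    sum(!is.na(o) & o > n_pre & o <= n_pre + n_step)
  }, integer(1))
  fired <- which(truth_counts > 0)
  rheobase <- if (length(fired) > 0) amps[min(fired)] else NA_real_

  gapfree <- NULL
  n_spont <- NA_integer_
  if (gapfree_s > 0) {
    n_gf <- round(gapfree_s * sr)
    gf_noise <- if (noisy) matrix(rnorm(n_gf, sd = config$noise_sd_mV), n_gf, 1) else NULL
    gf <- .adex_integrate(config, matrix(i_hold, n_gf, 1), v0, w0, gf_noise)
    gapfree <- as.vector(.render_spikes(gf$v, gf$events, config))
    gf_truth <- if (noisy) {
      .adex_integrate(config, matrix(i_hold, n_gf, 1), v0, w0, NULL)
    } else gf
    n_spont <- length(gf_truth$events[[1]])
  }

  rec <- sweep_recording(
    sweeps = v, amplitudes_pA = amps, sampling_rate_Hz = sr,
    step_start_s = protocol$step_start_s,
    step_duration_s = protocol$step_duration_s,
    holding_mode = protocol$holding_mode, gapfree = gapfree
  )
  truth <- list(
    rmp_mV = if (protocol$holding_mode == "resting") el else -75,
    rheobase_pA = rheobase,
    spikes_per_sweep = tibble(amplitude_pA = amps, n_spikes = truth_counts),
    n_spontaneous = n_spont
  )
  list(recording = rec, truth = truth)
}
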