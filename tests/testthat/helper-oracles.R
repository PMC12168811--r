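# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written as explicit per-element loops with
# no shared code paths.

# Per-frame predicate cell caller working directly on a raw trace.
naive_call <- function(raw, tl, p = responder_params()) {
  bw <- tl$baseline_window[1]:tl$baseline_window[2]
  b1m <- mean(raw[bw])
  dff <- (raw - b1m) / b1m
  b1sd <- sd(dff[bw])
  ww <- tl$wash_window[1]:tl$wash_window[2]
  b2m <- mean(dff[ww])
  b2sd <- sd(dff[ww])

  n_live <- 0L
  for (f in tl$kcl_window[1]:tl$kcl_window[2]) {
    if (dff[f] > b2m + p$k_sd * b2sd) n_live <- n_live + 1L
  }
  live <- n_live >= p$live_min_frames

  dw <- tl$compound_frame:(tl$wash_window[1] - 1L)
  thr <- if (p$responder_baseline == "baseline1") {
    p$k_sd * b1sd
  } else {
    b2m + p$k_sd * b2sd
  }
  n_supra <- 0L
  onset <- NA_integer_
  for (f in dw) {
    if (dff[f] > thr) {
      n_supra <- n_supra + 1L
      if (is.na(onset)) onset <- f
    }
  }
  responder <- FALSE
  if (live && n_supra >= p$responder_min_frames) {
    onset_s <- (onset - tl$compound_frame) * tl$frame_period_s
    if (onset_s <= p$onset_window_s) {
      peak <- -Inf
      for (f in onset:dw[length(dw)]) if (dff[f] > peak) peak <- dff[f]
      if (peak >= p$min_amplitude) responder <- TRUE
    }
  }
  list(live = live, responder = responder)
}

# Two-sided Fisher exact p by explicit enumeration with choose().
naive_fisher <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  n <- r1 + r2
  prob_of <- function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, prob_of, numeric(1))
  p_obs <- prob_of(a)
  total <- 0
  for (i in seq_along(ks)) if (probs[i] <= p_obs * (1 + 1e-7)) total <- total + probs[i]
  min(1, total)
}

# Exhaustive Mann-Whitney U count (larger-group convention of wilcox.test:
# U for the first sample).
naive_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) u <- u + 1 else if (xi == yi) u <- u + 0.5
  }
  u
}

# Naive dV/dt upstroke scan with the same merge rule as the detector.
naive_detect_onsets <- function(v, sr, thr = 10, min_ms = 2) {
  dt <- 1000 / sr
  onsets <- integer()
  prev <- -Inf
  last <- -Inf
  for (i in seq_len(length(v) - 1L)) {
    d <- (v[i + 1L] - v[i]) / dt
    if (d >= thr && prev < thr && (i - last) * dt >= min_ms) {
      onsets <- c(onsets, i)
      last <- i
    }
    prev <- d
  }
  onsets
}

# Step window of a recording in sample indices (first, last).
.step_samples_for_test <- function(rec) {
  n_pre <- round(rec$step_start_s * rec$sampling_rate_Hz)
  n_step <- round(rec$step_duration_s * rec$sampling_rate_Hz)
  c(n_pre + 1L, n_pre + n_step)
}

# A flat sweep with n triangular spikes pasted inside the step window.
make_spike_sweep <- function(n_spikes, sr = 10000, total_s = 0.8,
                             step_start_s = 0.3, step_dur_s = 0.2,
                             base_mV = -70) {
  v <- rep(base_mV, round(total_s * sr))
  if (n_spikes > 0) {
    w <- round(0.002 * sr)
    starts <- round(step_start_s * sr) +
      round(seq(0.02, step_dur_s - 0.02, length.out = n_spikes) * sr)
    for (s0 in starts) {
      up <- s0:(s0 + w)
      v[up] <- base_mV + (30 - base_mV) * (up - s0) / w
      dn <- (s0 + w):(s0 + 2 * w)
      v[dn] <- 30 + (base_mV - 30) * (dn - (s0 + w)) / w
    }
  }
  v
}
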