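test_that("LJP correction shifts potentials once and only once", {
  rec <- sweep_recording(matrix(-70, 100, 2), c(0, 25), 1000, 0.05, 0.02,
                         ljp_mV = -14, gapfree = rep(-70, 50))
  cor <- correct_ljp(rec)
  expect_true(all(cor$sweeps == -84))
  expect_true(all(cor$gapfree == -84))
  expect_error(correct_ljp(cor), "twice")

  rec0 <- sweep_recording(matrix(-70, 100, 1), 0, 1000, 0.05, 0.02, ljp_mV = 0)
  expect_true(all(correct_ljp(rec0)$sweeps == -70))
})

test_that("AP detection finds upstrokes and matches the naive crossing scan", {
  expect_identical(nrow(detect_aps(rep(-70, 1000), 10000)), 0L)
  # 20 mV/ms ramp: a single crossing at the first sample pair
  ramp <- seq(-70, by = 2, length.out = 200)  # 2 mV per 0.1 ms sample
  ev <- detect_aps(ramp, 10000)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$onset_idx, 1L)

  set.seed(55)
  for (i in 1:10) {
    v <- make_spike_sweep(sample(0:5, 1)) + rnorm(8000, sd = 0.05)
    ev <- detect_aps(v, 10000)
    expect_identical(ev$onset_idx, naive_detect_onsets(v, 10000))
  }
  expect_error(detect_aps(-70, 10000), "2 samples")
})

test_that("AP count never increases with a higher dV/dt threshold", {
  set.seed(66)
  for (i in 1:5) {
    v <- make_spike_sweep(sample(1:5, 1)) + rnorm(8000, sd = 0.3)
    counts <- vapply(c(5, 10, 20, 40, 80), function(thr) {
      nrow(detect_aps(v, 10000, ap_detection_params(dvdt_threshold_mV_per_ms = thr)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("RMP is the mean over the 200 ms pre-stimulus window", {
  v <- rep(-70, 8000)
  expect_equal(measure_rmp(v, 10000, 0.3), -70)
  cfg <- neuron_sim_config(leak_reversal_mV = -65, seed = 1)
  sim <- gen_current_clamp(cfg, sweep_protocol(amplitudes_pA = c(0, 25)))
  expect_equal(measure_rmp(sim$recording$sweeps[, 1], cfg$sampling_rate_Hz, 0.3),
               -65, tolerance = 0.01)
  expect_error(measure_rmp(rep(-70, 1000), 10000, 0.1), "pre-stimulus")
})

test_that("rheobase is the minimum amplitude with an AP, by exhaustive check", {
  cfg <- neuron_sim_config(seed = 4)
  sim <- gen_current_clamp(cfg)
  rec <- sim$recording
  expect_equal(measure_rheobase(rec), sim$truth$rheobase_pA)
  fi <- count_step_aps(rec)
  fired <- fi$amplitude_pA[fi$n_aps > 0]
  expect_equal(measure_rheobase(rec), min(fired))
  expect_true(all(fi$n_aps[fi$amplitude_pA < min(fired)] == 0L))
  expect_true(measure_rheobase(rec) %in% rec$amplitudes_pA)
})

test_that("waveform features follow piecewise-linear geometry exactly", {
  # triangular spike from -75: 2 ms rise to +25, 2 ms fall; amplitude 100,
  # half level -25 crossed 1 ms into the rise and 1 ms into the fall
  sr <- 10000
  v <- rep(-75, 8000)
  s0 <- 3501L
  w <- round(0.002 * sr)
  v[s0:(s0 + w)] <- -75 + 100 * (0:w) / w
  v[(s0 + w):(s0 + 2 * w)] <- 25 - 100 * (0:w) / w
  rec <- sweep_recording(matrix(v), 100, sr, 0.3, 0.2, holding_mode = "held_minus75")
  f <- waveform_features(rec)
  expect_equal(f$peak_amplitude_mV, 100)
  expect_equal(f$half_width_ms, 2.0, tolerance = 0.01)
  expect_equal(f$time_to_peak_ms, (s0 + w - 3000) / 10, tolerance = 0.2)
  expect_equal(f$fahp_mV, -75)

  expect_error(waveform_features(
    sweep_recording(matrix(-75, 8000, 1), 100, sr, 0.3, 0.2)), "undefined")
})

test_that("AP threshold is the potential at the first dV/dt crossing", {
  sr <- 20000
  v <- rep(-60, 16000)
  # slow 5 mV/ms creep from -60 to -45, then 50 mV/ms upstroke to +20
  creep <- seq(-60, -45, by = 5 / sr * 1000)
  burst <- seq(-45, 20, by = 50 / sr * 1000)
  s0 <- 7001L
  seg <- c(creep, burst)
  v[s0:(s0 + length(seg) - 1L)] <- seg
  v[(s0 + length(seg)):16000] <- -60
  rec <- sweep_recording(matrix(v), 200, sr, 0.3, 0.2)
  f <- waveform_features(rec)
  expect_equal(f$threshold_mV, -45, tolerance = 0.3)
})

test_that("fast AHP is the window minimum between peak and the next event", {
  cfg <- neuron_sim_config(seed = 9)
  sim <- gen_current_clamp(cfg, sweep_protocol(holding_mode = "held_minus75"))
  rec <- sim$recording
  f <- waveform_features(rec)
  s <- which(rec$amplitudes_pA == f$sweep_amplitude_pA)
  v <- rec$sweeps[, s]
  ev <- detect_aps(v, rec$sampling_rate_Hz)
  win <- .step_samples_for_test(rec)
  ev <- ev[ev$onset_idx >= win[1] & ev$onset_idx <= win[2], ]
  stop_at <- if (nrow(ev) > 1) ev$onset_idx[2] else win[2]
  mn <- Inf
  for (k in (ev$peak_idx[1] + 1L):stop_at) if (v[k] < mn) mn <- v[k]
  expect_equal(f$fahp_mV, mn)
  # mAHP: minimum in the 200 ms after step offset
  mn2 <- min(v[(win[2] + 1L):(win[2] + round(0.2 * rec$sampling_rate_Hz))])
  expect_equal(f$mahp_mV, mn2)
})

test_that("firing classification follows the stated decision rules", {
  mk <- function(counts, gapfree = NULL) {
    sw <- vapply(counts, make_spike_sweep, numeric(8000))
    sweep_recording(sw, seq(0, by = 25, length.out = length(counts)),
                    10000, 0.3, 0.2, gapfree = gapfree)
  }
  r <- classify_firing(mk(c(0, 0, 1, 1, 1)))
  expect_identical(r$firing_pattern, "single")
  expect_identical(r$max_aps, 1L)
  expect_true(is.na(r$spontaneous))
  expect_identical(classify_firing(mk(c(0, 1, 3)))$firing_pattern, "multiple")
  expect_identical(classify_firing(mk(c(0, 0)))$firing_pattern, "none")
  # spontaneous: at least one AP in the gap-free segment
  quiet <- rep(-70, 5000)
  expect_false(classify_firing(mk(c(0, 1), gapfree = quiet))$spontaneous)
  one_ap <- make_spike_sweep(1)
  expect_true(classify_firing(mk(c(0, 1), gapfree = one_ap))$spontaneous)
})

test_that("exclusion rules fire on non-firing and depolarised cells", {
  e1 <- apply_exclusions(list(rmp_mV = -35, rheobase_pA = 200))
  expect_true(e1$excluded)
  expect_identical(e1$reason, "depolarised RMP")
  e2 <- apply_exclusions(list(rmp_mV = -60, rheobase_pA = NA_real_))
  expect_true(e2$excluded)
  expect_identical(e2$reason, "non-firing")
  e3 <- apply_exclusions(list(rmp_mV = -60, rheobase_pA = 200))
  expect_false(e3$excluded)
  expect_true(is.na(e3$reason))
})

test_that("LJP correction shifts voltage features and leaves time features alone", {
  cfg <- neuron_sim_config(seed = 12)
  rest <- gen_current_clamp(cfg)$recording
  held <- gen_current_clamp(cfg, sweep_protocol(holding_mode = "held_minus75"))$recording
  before <- ephys_features(rest, held)
  after <- ephys_features(correct_ljp(rest), correct_ljp(held))
  for (col in c("rmp_mV", "threshold_mV", "fahp_mV", "mahp_mV")) {
    expect_equal(after[[col]], before[[col]] - 14, tolerance = 1e-9)
  }
  for (col in c("rheobase_pA", "half_width_ms", "time_to_peak_ms",
                "peak_amplitude_mV", "max_aps")) {
    expect_equal(after[[col]], before[[col]], tolerance = 1e-9)
  }
  expect_identical(after$fi[[1]], before$fi[[1]])
})

test_that("half-width and time-to-peak are stable under time-axis dilation", {
  mk_tri <- function(sr) {
    v <- rep(-75, round(0.8 * sr))
    s0 <- round(0.35 * sr) + 1L
    w <- round(0.002 * sr)
    v[s0:(s0 + w)] <- -75 + 100 * (0:w) / w
    v[(s0 + w):(s0 + 2 * w)] <- 25 - 100 * (0:w) / w
    sweep_recording(matrix(v), 100, sr, 0.3, 0.2)
  }
  f1 <- waveform_features(mk_tri(10000))
  f2 <- waveform_features(mk_tri(20000))
  expect_equal(f1$half_width_ms, f2$half_width_ms, tolerance = 0.01)
  expect_equal(f1$time_to_peak_ms, f2$time_to_peak_ms, tolerance = 0.1)
})

test_that("simulator cohorts recover RMP and rheobase", {
  set.seed(301)
  for (i in 1:6) {
    cfg <- neuron_sim_config(
      leak_reversal_mV = runif(1, -70, -60),
      leak_conductance_nS = runif(1, 8, 14),
      capacitance_pF = runif(1, 120, 200),
      spike_threshold_mV = runif(1, -52, -46),
      seed = 300 + i
    )
    sim <- gen_current_clamp(cfg)
    rec <- sim$recording
    expect_lt(abs(measure_rmp(rec$sweeps[, 1], cfg$sampling_rate_Hz, 0.3) -
                    cfg$leak_reversal_mV), 1)
    expect_identical(measure_rheobase(rec), sim$truth$rheobase_pA)
    fi <- count_step_aps(rec)
    expect_identical(fi$n_aps, sim$truth$spikes_per_sweep$n_spikes)
  }
})

test_that("sweep recordings round-trip through their text representation", {
  cfg <- neuron_sim_config(seed = 17)
  sim <- gen_current_clamp(cfg, sweep_protocol(amplitudes_pA = seq(0, 100, 50)),
                           gapfree_s = 0.3)
  stem <- file.path(withr::local_tempdir(), "cell01")
  write_sweep_recording(sim$recording, stem)
  back <- read_sweep_recording(stem)
  expect_equal(back$sweeps, sim$recording$sweeps, tolerance = 1e-12)
  expect_equal(back$amplitudes_pA, sim$recording$amplitudes_pA)
  expect_equal(back$gapfree, sim$recording$gapfree, tolerance = 1e-12)
  expect_identical(count_step_aps(back), count_step_aps(sim$recording))
})
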