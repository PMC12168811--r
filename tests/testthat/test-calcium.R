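# Shared engineered timeline: 1 s frames, baseline 60, drug 420, wash 60,
# KCl 60. Constant-baseline traces make every threshold exact.
eng_tl <- acquisition_timeline(
  frame_period_s = 1, baseline_window = c(1L, 60L), compound_frame = 61L,
  wash_window = c(481L, 540L), kcl_window = c(541L, 600L), n_frames = 600L
)

eng_trace <- function(n_drug_frames = 0L, onset_rel = 60L, drug_amp = 0.2,
                      n_kcl_frames = 0L, kcl_amp = 0.5, f0 = 100) {
  raw <- rep(f0, eng_tl$n_frames)
  if (n_drug_frames > 0) {
    idx <- (eng_tl$compound_frame + onset_rel) + seq_len(n_drug_frames) - 1L
    raw[idx] <- f0 * (1 + drug_amp)
  }
  if (n_kcl_frames > 0) {
    idx <- eng_tl$kcl_window[1] + seq_len(n_kcl_frames) - 1L
    raw[idx] <- f0 * (1 + kcl_amp)
  }
  raw
}

test_that("trace extraction averages label pixels exactly", {
  movie <- array(7, dim = c(4, 5, 3))
  labels <- matrix(0L, 4, 5)
  labels[1:2, 1:2] <- 1L
  labels[4, 5] <- 2L
  tr <- extract_roi_traces(movie, labels)
  expect_true(all(tr$raw_f == 7))
  expect_identical(sort(unique(tr$roi_id)), c(1L, 2L))

  set.seed(5)
  movie <- array(runif(6 * 6 * 4, 10, 100), dim = c(6, 6, 4))
  labels <- matrix(sample(0:5, 36, replace = TRUE), 6, 6)
  tr <- extract_roi_traces(movie, labels)
  # naive per-pixel loop oracle
  for (id in sort(unique(labels[labels > 0]))) {
    for (f in 1:4) {
      acc <- 0; cnt <- 0
      for (i in 1:6) for (j in 1:6) {
        if (labels[i, j] == id) { acc <- acc + movie[i, j, f]; cnt <- cnt + 1 }
      }
      got <- tr$raw_f[tr$roi_id == id & tr$frame == f]
      expect_equal(got, acc / cnt, tolerance = 1e-9)
    }
  }
  # single-pixel ROI is the pixel's own time series
  labels1 <- matrix(0L, 6, 6); labels1[3, 4] <- 9L
  tr1 <- extract_roi_traces(movie, labels1)
  expect_equal(tr1$raw_f, movie[3, 4, ])

  expect_error(extract_roi_traces(movie, matrix(1L, 3, 3)), "dimensions")
  expect_error(extract_roi_traces(movie, matrix(0L, 6, 6)), "no ROIs")
})

test_that("dF/F follows the baseline-normalisation formula", {
  raw <- rep(100, eng_tl$n_frames)
  d <- compute_dff(raw, eng_tl)
  expect_true(all(d$dff == 0))
  expect_equal(d$baseline1_sd, 0)
  expect_equal(d$baseline2_sd, 0)

  raw[200] <- 110
  d <- compute_dff(raw, eng_tl)
  expect_equal(d$dff[200], 0.10)

  set.seed(9)
  raw <- runif(eng_tl$n_frames, 50, 150)
  d <- compute_dff(raw, eng_tl)
  b1 <- mean(raw[1:60])
  for (f in c(1, 77, 300, 600)) {
    expect_equal(d$dff[f], (raw[f] - b1) / b1, tolerance = 1e-12)
  }
  expect_error(compute_dff(rep(0, 600), eng_tl), "baseline")
  expect_error(compute_dff(rep(-5, 600), eng_tl), "baseline")
})

test_that("max response averages the three maximal values", {
  expect_equal(max_response(c(0.5, 0.4, 0.3, 0.2)), 0.4)
  expect_equal(max_response(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(max_response(c(0.7, 0.1)), 0.4)
  expect_error(max_response(numeric()), "Empty")
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(3:50, 1))
    expect_equal(max_response(x), mean(sort(x, decreasing = TRUE)[1:3]))
  }
})

test_that("live and responder frame-count boundaries are exact", {
  p <- responder_params()
  call80 <- call_cell(compute_dff(eng_trace(80, n_kcl_frames = 20), eng_tl), eng_tl, p)
  expect_true(call80$responder)
  call79 <- call_cell(compute_dff(eng_trace(79, n_kcl_frames = 20), eng_tl), eng_tl, p)
  expect_false(call79$responder)
  expect_identical(call79$reason, "insufficient-frames")

  live10 <- call_cell(compute_dff(eng_trace(0, n_kcl_frames = 10), eng_tl), eng_tl, p)
  expect_true(live10$live)
  live9 <- call_cell(compute_dff(eng_trace(0, n_kcl_frames = 9), eng_tl), eng_tl, p)
  expect_false(live9$live)
  expect_identical(live9$reason, "dead")
})

test_that("the five-minute onset window flips the responder call", {
  p <- responder_params()
  on299 <- call_cell(compute_dff(eng_trace(100, onset_rel = 299, n_kcl_frames = 20),
                                 eng_tl), eng_tl, p)
  expect_true(on299$responder)
  on301 <- call_cell(compute_dff(eng_trace(100, onset_rel = 301, n_kcl_frames = 20),
                                 eng_tl), eng_tl, p)
  expect_false(on301$responder)
  expect_identical(on301$reason, "late-onset")
})

test_that("the 10% amplitude floor rejects suprathreshold but shallow responses", {
  p <- responder_params()
  shallow <- call_cell(compute_dff(eng_trace(100, drug_amp = 0.05,
                                             n_kcl_frames = 20), eng_tl),
                       eng_tl, p)
  expect_true(shallow$live)
  expect_false(shallow$responder)
  expect_identical(shallow$reason, "sub-amplitude")
  # a dead cell is a non-responder with reason "dead", never an error
  dead <- call_cell(compute_dff(eng_trace(100), eng_tl), eng_tl, p)
  expect_false(dead$live)
  expect_identical(dead$reason, "dead")
})

test_that("calls are scale invariant in the raw fluorescence", {
  set.seed(21)
  co <- gen_calcium_cohort(calcium_sim_config(n_cells = 25, seed = 8))
  for (c_mult in c(0.01, 3, 1e4)) {
    scaled <- co$traces
    scaled$raw_f <- scaled$raw_f * c_mult
    a <- classify_cells(co$traces, co$timeline)
    b <- classify_cells(scaled, co$timeline)
    expect_identical(a$live, b$live)
    expect_identical(a$responder, b$responder)
    expect_equal(a$max_pct_response, b$max_pct_response, tolerance = 1e-9)
  }
})

test_that("raising thresholds never converts a non-responder into a responder", {
  set.seed(31)
  co <- gen_calcium_cohort(calcium_sim_config(
    n_cells = 40, noise_sd = 0.05, response_margin = 1, seed = 14))
  base <- classify_cells(co$traces, co$timeline, responder_params())
  for (p2 in list(responder_params(k_sd = 4), responder_params(k_sd = 6),
                  responder_params(responder_min_frames = 100),
                  responder_params(responder_min_frames = 150))) {
    harder <- classify_cells(co$traces, co$timeline, p2)
    expect_true(all(harder$responder <= base$responder))
  }
})

test_that("vectorised classifier matches the scalar caller and responders are live", {
  set.seed(77)
  cfg <- calcium_sim_config(n_cells = 60, noise_sd = 0.04,
                            response_margin = 1, seed = 19)
  co <- gen_calcium_cohort(cfg)
  vec <- classify_cells(co$traces, co$timeline)
  expect_true(all(vec$live[vec$responder]))
  for (id in co$truth$roi_id) {
    raw <- co$traces$raw_f[co$traces$roi_id == id]
    one <- call_cell(compute_dff(raw, co$timeline), co$timeline)
    row <- vec[vec$roi_id == id, ]
    expect_identical(row$live, one$live)
    expect_identical(row$responder, one$responder)
    expect_identical(row$reason, one$reason)
    expect_equal(row$max_pct_response, one$max_pct_response)
  }
})

test_that("transient characterisation labels the generator archetypes", {
  tl <- default_timeline()
  on <- tl$compound_frame + 4L
  lab <- function(a) {
    raw <- 100 * (1 + gen_transient(a, 0.6, on, tl))
    characterize_transient(compute_dff(raw, tl), tl)
  }
  expect_identical(lab("rapid")$archetype, "rapid")
  expect_identical(lab("slow")$archetype, "slow")
  expect_identical(lab("intermediate")$archetype, "intermediate")
  osc <- lab("oscillatory")
  expect_identical(osc$archetype, "oscillatory")
  expect_gte(osc$peak_count, 3L)
  # monotone plateau never decays: unclassified
  raw <- rep(100, tl$n_frames)
  dw <- drug_window(tl)
  raw[dw] <- 100 * (1 + 0.5 * seq_along(dw) / length(dw))
  expect_identical(characterize_transient(compute_dff(raw, tl), tl)$archetype,
                   "unclassified")
  # non-responders have no defined features
  expect_error(
    characterize_transient(compute_dff(raw, tl), tl,
                           call = tibble::tibble(responder = FALSE)),
    "undefined"
  )
})

test_that("coverslip summaries count live and responder percentages", {
  co <- gen_calcium_cohort(calcium_sim_config(
    n_cells = 100, frac_dead = 0.1, frac_responders_among_live = 0.4, seed = 7))
  calls <- classify_cells(co$traces, co$timeline)
  s <- summarize_coverslip(calls)
  expect_equal(s$pct_live, 90)
  expect_equal(s$pct_responders, 40)

  dead <- gen_calcium_cohort(calcium_sim_config(n_cells = 10, frac_dead = 1, seed = 3))
  s0 <- summarize_coverslip(classify_cells(dead$traces, dead$timeline))
  expect_equal(s0$pct_live, 0)
  expect_true(is.na(s0$pct_responders))
  expect_true(s0$no_live_cells)

  one <- calls[which(calls$responder)[1], ]
  s1 <- summarize_coverslip(one)
  expect_equal(s1$mean_max_response, one$max_pct_response)
  expect_error(summarize_coverslip(calls[0, ]), "No cell calls")
})
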