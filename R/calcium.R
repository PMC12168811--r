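#' Responder-calling parameters
#'
#' Thresholds of the live-cell and responder criteria. A cell is live when at
#' least `live_min_frames` frames of the KCl epoch exceed the second (wash)
#' baseline by `k_sd` standard deviations. A live cell is a drug responder
#' when at least `responder_min_frames` drug-epoch frames exceed the
#' pre-compound baseline (in dF/F space) by `k_sd` SD, the first
#' suprathreshold frame falls within `onset_window_s` of compound
#' application, and the response reaches at least `min_amplitude` dF/F.
#'
#' @param k_sd SD multiplier of both criteria (default 3).
#' @param live_min_frames Minimum suprathreshold KCl frames (default 10).
#' @param responder_min_frames Minimum suprathreshold drug-epoch frames
#'   (default 80, about two minutes at a 1.5 s frame period). Frames are
#'   counted cumulatively, not consecutively.
#' @param onset_window_s Maximum latency of the first suprathreshold frame
#'   after compound application, seconds (default 300).
#' @param min_amplitude Minimum peak dF/F of a response (default 0.10).
#' @param responder_baseline Which baseline supplies the mean/SD of the
#'   responder predicate: `"baseline1"` (pre-compound, in dF/F space; the
#'   default) or `"baseline2"` (wash). Both readings of the criterion are
#'   exposed because either is defensible; see the methods vignette.
#' @return A list of class `responder_params`.
#' @export
responder_params <- function(k_sd = 3, live_min_frames = 10L,
                             responder_min_frames = 80L,
                             onset_window_s = 300, min_amplitude = 0.10,
                             responder_baseline = c("baseline1", "baseline2")) {
  responder_baseline <- match.arg(responder_baseline)
  if (k_sd <= 0 || live_min_frames <= 0 || responder_min_frames <= 0 ||
      onset_window_s <= 0) {
    abort("All responder parameters must be positive.")
  }
  if (min_amplitude <= 0 || min_amplitude > 1) {
    abort("`min_amplitude` must lie in (0, 1].")
  }
  structure(
    list(
      k_sd = k_sd,
      live_min_frames = as.integer(live_min_frames),
      responder_min_frames = as.integer(responder_min_frames),
      onset_window_s = onset_window_s,
      min_amplitude = min_amplitude,
      responder_baseline = responder_baseline
    ),
    class = "responder_params"
  )
}

#' Extract per-ROI mean-intensity traces from a movie and a label mask
#'
#' Consumes a segmentation label mask (e.g. exported from StarDist) and
#' averages pixel intensity over each label for every frame. Label 0 is
#' background and is ignored.
#'
#' @param movie Numeric array `height x width x frames`, or a `height x width`
#'   matrix for a single frame.
#' @param labels Integer matrix of the same spatial dimensions; positive
#'   values are ROI ids.
#' @return A tibble with columns `roi_id`, `frame`, `raw_f` (long format).
#' @export
extract_roi_traces <- function(movie, labels) {
  if (is.matrix(movie)) movie <- array(movie, dim = c(dim(movie), 1L))
  if (length(dim(movie)) != 3L) abort("`movie` must be a h x w x t array.")
  if (!all(dim(labels) == dim(movie)[1:2])) {
    abort("`labels` and `movie` differ in spatial dimensions.")
  }
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L) abort("Label mask contains no ROIs.")
  n_t <- dim(movie)[3]
  flat <- matrix(movie, nrow = prod(dim(movie)[1:2]), ncol = n_t)
  lab_vec <- as.integer(labels)
  keep <- lab_vec > 0L
  # per-frame group means over label pixels: rowsum is one pass per frame set
  sums <- rowsum(flat[keep, , drop = FALSE], group = lab_vec[keep])
  counts <- as.vector(table(lab_vec[keep]))
  means <- sums / counts
  tibble(
    roi_id = rep(as.integer(rownames(sums)), times = n_t),
    frame = rep(seq_len(n_t), each = nrow(sums)),
    raw_f = as.vector(means)
  ) %>% arrange(.data$roi_id, .data$frame)
}

#' Compute dF/F and dual baseline statistics for one trace
#'
#' dF/F at frame t is `(F[t] - B1) / B1` where `B1` is the mean raw
#' fluorescence over the pre-compound baseline window. A second baseline
#' (mean and SD of dF/F) is computed over the wash window just before KCl.
#'
#' @param raw_f Numeric vector of raw fluorescence (or Fura-2 ratio) values,
#'   one per frame.
#' @param timeline An [acquisition_timeline()].
#' @return A list of class `dff_trace` with fields `dff`, `baseline1_mean`,
#'   `baseline1_sd` (raw units), `baseline2_mean`, `baseline2_sd` (dF/F
#'   units), and `baseline1_dff_sd` (SD of dF/F over the baseline window).
#' @export
compute_dff <- function(raw_f, timeline) {
  if (length(raw_f) < timeline$n_frames) {
    abort("Trace shorter than the timeline's frame count.")
  }
  bw <- seq.int(timeline$baseline_window[1], timeline$baseline_window[2])
  b1m <- mean(raw_f[bw])
  if (!is.finite(b1m) || b1m <= 0) {
    abort("Degenerate baseline: baseline1 mean must be positive.")
  }
  dff <- (raw_f - b1m) / b1m
  ww <- seq.int(timeline$wash_window[1], timeline$wash_window[2])
  structure(
    list(
      dff = dff,
      baseline1_mean = b1m,
      baseline1_sd = stats::sd(raw_f[bw]),
      baseline1_dff_sd = stats::sd(dff[bw]),
      baseline2_mean = mean(dff[ww]),
      baseline2_sd = stats::sd(dff[ww])
    ),
    class = "dff_trace"
  )
}

#' Mean of the three largest values in a response window
#'
#' The "max % response" summary: the three maximal dF/F values over the
#' response timeframe are averaged. Windows with fewer than three frames are
#' averaged whole.
#'
#' @param values Numeric vector (dF/F over the response window).
#' @return A single number.
#' @export
max_response <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("Empty response window.")
  mean(sort(values, decreasing = TRUE)[seq_len(min(3L, length(values)))])
}

# Internal: shared predicate arithmetic. Returns the per-trace call given the
# dff object. Used by both the scalar and the vectorised entry points.
.call_one <- function(d, timeline, params) {
  kcl <- seq.int(timeline$kcl_window[1], timeline$kcl_window[2])
  live_thr <- d$baseline2_mean + params$k_sd * d$baseline2_sd
  n_live_frames <- sum(d$dff[kcl] > live_thr)
  live <- n_live_frames >= params$live_min_frames

  dw <- drug_window(timeline)
  if (params$responder_baseline == "baseline1") {
    resp_thr <- 0 + params$k_sd * d$baseline1_dff_sd
  } else {
    resp_thr <- d$baseline2_mean + params$k_sd * d$baseline2_sd
  }
  supra <- d$dff[dw] > resp_thr
  n_supra <- sum(supra)
  onset_frame <- if (n_supra > 0L) dw[which(supra)[1]] else NA_integer_

  responder <- FALSE
  reason <- NA_character_
  max_pct <- NA_real_
  if (!live) {
    reason <- "dead"
  } else if (n_supra < params$responder_min_frames) {
    reason <- "insufficient-frames"
  } else {
    onset_s <- (onset_frame - timeline$compound_frame) * timeline$frame_period_s
    resp_win <- seq.int(onset_frame, dw[length(dw)])
    max_pct <- max_response(d$dff[resp_win])
    if (onset_s > params$onset_window_s) {
      reason <- "late-onset"
    } else if (max(d$dff[resp_win]) < params$min_amplitude) {
      reason <- "sub-amplitude"
      max_pct <- NA_real_
    } else {
      responder <- TRUE
    }
  }
  if (!responder) max_pct <- NA_real_
  tibble(
    live = live, responder = responder,
    n_live_frames = n_live_frames, n_supra_frames = n_supra,
    onset_frame = onset_frame, max_pct_response = max_pct, reason = reason
  )
}

#' Call one cell live/dead and responder/non-responder
#'
#' Applies the KCl live-cell criterion and the three-part responder criterion
#' (suprathreshold frame count, onset latency, minimum amplitude) to a single
#' dF/F trace. A dead cell is reported as a non-responder with reason
#' `"dead"`; no error is raised.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param timeline An [acquisition_timeline()].
#' @param params A [responder_params()].
#' @return A one-row tibble: `live`, `responder`, `n_live_frames`,
#'   `n_supra_frames`, `onset_frame`, `max_pct_response` (mean of the three
#'   maximal dF/F values from onset to the end of the drug epoch; `NA` for
#'   non-responders), `reason` (`NA` for responders, else one of `"dead"`,
#'   `"insufficient-frames"`, `"late-onset"`, `"sub-amplitude"`).
#' @export
call_cell <- function(dff, timeline, params = responder_params()) {
  stopifnot(inherits(dff, "dff_trace"))
  .call_one(dff, timeline, params)
}

#' Classify every ROI of a trace table
#'
#' Vectorised cell caller: pivots the long trace table to a ROI-by-frame
#' matrix and evaluates all baseline statistics and criteria with matrix
#' arithmetic, so cohorts of thousands of traces classify in milliseconds.
#' Produces exactly the calls [call_cell()] makes trace by trace.
#'
#' @param traces Tibble with columns `roi_id`, `frame`, `raw_f`.
#' @param timeline An [acquisition_timeline()].
#' @param params A [responder_params()].
#' @return A tibble with one row per ROI (columns of [call_cell()] plus
#'   `roi_id`, `baseline1_mean`).
#' @export
classify_cells <- function(traces, timeline, params = responder_params()) {
  stopifnot(all(c("roi_id", "frame", "raw_f") %in% names(traces)))
  traces <- arrange(traces, .data$roi_id, .data$frame)
  ids <- unique(traces$roi_id)
  n_t <- timeline$n_frames
  if (nrow(traces) != length(ids) * n_t) {
    abort("Trace table is not complete: need every frame 1..n_frames per ROI.")
  }
  f <- matrix(traces$raw_f, nrow = length(ids), ncol = n_t, byrow = TRUE)

  bw <- seq.int(timeline$baseline_window[1], timeline$baseline_window[2])
  b1m <- rowMeans(f[, bw, drop = FALSE])
  if (any(b1m <= 0)) abort("Degenerate baseline: baseline1 mean must be positive.")
  dff <- (f - b1m) / b1m
  row_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  }
  b1sd_dff <- row_sd(dff[, bw, drop = FALSE])
  ww <- seq.int(timeline$wash_window[1], timeline$wash_window[2])
  b2m <- rowMeans(dff[, ww, drop = FALSE])
  b2sd <- row_sd(dff[, ww, drop = FALSE])

  kcl <- seq.int(timeline$kcl_window[1], timeline$kcl_window[2])
  n_live_frames <- rowSums(dff[, kcl, drop = FALSE] > b2m + params$k_sd * b2sd)
  live <- n_live_frames >= params$live_min_frames

  dw <- drug_window(timeline)
  resp_thr <- if (params$responder_baseline == "baseline1") {
    params$k_sd * b1sd_dff
  } else {
    b2m + params$k_sd * b2sd
  }
  supra <- dff[, dw, drop = FALSE] > resp_thr
  n_supra <- rowSums(supra)
  first_idx <- apply(supra, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
  onset_frame <- dw[1] - 1L + first_idx
  onset_s <- (onset_frame - timeline$compound_frame) * timeline$frame_period_s

  end_dw <- dw[length(dw)]
  max_pct <- rep(NA_real_, length(ids))
  peak <- rep(NA_real_, length(ids))
  for (i in which(!is.na(onset_frame))) {
    win <- dff[i, seq.int(onset_frame[i], end_dw)]
    peak[i] <- max(win)
    max_pct[i] <- mean(sort(win, decreasing = TRUE)[seq_len(min(3L, length(win)))])
  }

  enough <- n_supra >= params$responder_min_frames
  on_time <- !is.na(onset_s) & onset_s <= params$onset_window_s
  big <- !is.na(peak) & peak >= params$min_amplitude
  responder <- live & enough & on_time & big
  reason <- rep(NA_character_, length(ids))
  reason[!live] <- "dead"
  reason[live & !enough] <- "insufficient-frames"
  reason[live & enough & !on_time] <- "late-onset"
  reason[live & enough & on_time & !big] <- "sub-amplitude"
  max_pct[!responder] <- NA_real_

  tibble(
    roi_id = ids, live = live, responder = responder,
    n_live_frames = as.integer(n_live_frames),
    n_supra_frames = as.integer(n_supra),
    onset_frame = as.integer(onset_frame),
    max_pct_response = max_pct, reason = reason,
    baseline1_mean = b1m
  )
}

#' Descriptive shape features of a responder transient
#'
#' Reports peak count, time to peak, and post-peak half-decay time over the
#' drug epoch, and assigns a descriptive archetype label (`slow`,
#' `intermediate`, `rapid`, `oscillatory`, or `unclassified`). The label is
#' purely descriptive and never feeds responder classification. Peaks are
#' local maxima reaching at least half of the window maximum; the archetype
#' cutoffs (half-decay >= 40 s slow, 10-40 s intermediate, < 10 s rapid, >= 3
#' peaks oscillatory) are documented heuristics.
#'
#' @param dff A `dff_trace`.
#' @param timeline An `acq_timeline`.
#' @param call Optional one-row call result for this trace; if supplied and
#'   not a responder, an error is raised (features are undefined).
#' @return A one-row tibble: `peak_count`, `time_to_peak_s`,
#'   `half_decay_s`, `archetype`.
#' @export
characterize_transient <- function(dff, timeline, call = NULL) {
  if (!is.null(call) && !isTRUE(call$responder[1])) {
    abort("Transient features are undefined for non-responders.")
  }
  dw <- drug_window(timeline)
  y <- dff$dff[dw]
  fp <- timeline$frame_period_s
  n <- length(y)
  top <- max(y)
  # local maxima at >= 50% of the window max, interior frames only
  is_peak <- logical(n)
  if (n >= 3L) {
    core <- 2:(n - 1L)
    is_peak[core] <- y[core] > y[core - 1L] & y[core] >= y[core + 1L] &
      y[core] >= 0.5 * top
  }
  peak_count <- sum(is_peak)
  gpk <- which.max(y)
  time_to_peak_s <- (dw[gpk] - timeline$compound_frame) * fp
  after <- y[seq.int(gpk, n)]
  below <- which(after <= top / 2)
  half_decay_s <- if (length(below) > 0L) (below[1] - 1L) * fp else NA_real_
  archetype <- if (peak_count >= 3L) {
    "oscillatory"
  } else if (is.na(half_decay_s)) {
    "unclassified"
  } else if (half_decay_s >= 40) {
    "slow"
  } else if (half_decay_s >= 10) {
    "intermediate"
  } else {
    "rapid"
  }
  tibble(
    peak_count = as.integer(peak_count),
    time_to_peak_s = time_to_peak_s,
    half_decay_s = half_decay_s,
    archetype = archetype
  )
}

#' Summarise cell calls per coverslip
#'
#' Each coverslip is an independent experimental unit: live and responder
#' percentages plus the mean and median max response among responders.
#'
#' @param calls Tibble of per-ROI calls from [classify_cells()].
#' @return One-row tibble: `n_rois`, `n_live`, `n_responders`, `pct_live`,
#'   `pct_responders` (of live; `NA` with `no_live_cells = TRUE` when the
#'   coverslip has no live cells), `mean_max_response`, `median_max_response`.
#' @export
summarize_coverslip <- function(calls) {
  if (nrow(calls) == 0L) abort("No cell calls to summarise.")
  n <- nrow(calls)
  n_live <- sum(calls$live)
  n_resp <- sum(calls$responder)
  mm <- calls$max_pct_response[calls$responder]
  tibble(
    n_rois = n,
    n_live = n_live,
    n_responders = n_resp,
    pct_live = 100 * n_live / n,
    pct_responders = if (n_live > 0L) 100 * n_resp / n_live else NA_real_,
    no_live_cells = n_live == 0L,
    mean_max_response = if (n_resp > 0L) mean(mm) else NA_real_,
    median_max_response = if (n_resp > 0L) stats::median(mm) else NA_real_
  )
}
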