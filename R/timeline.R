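#' Acquisition timeline for a calcium-imaging recording
#'
#' Describes the epoch structure of one time-lapse recording: a pre-compound
#' baseline, a drug (compound) epoch, a wash, and a terminal high-KCl
#' depolarisation epoch used as the live-cell positive control. All windows
#' are 1-based inclusive frame intervals `c(first, last)` and must be ordered
#' `baseline < compound <= wash < kcl` without overlap.
#'
#' @param frame_period_s Seconds between consecutive frames (> 0).
#' @param baseline_window Integer frame interval of the pre-compound baseline.
#' @param compound_frame Frame index at which the compound is applied. Frames
#'   from `compound_frame` up to (but not including) the wash window form the
#'   drug epoch.
#' @param wash_window Integer frame interval of the wash, just before KCl;
#'   the second baseline is computed here.
#' @param kcl_window Integer frame interval of the 50 mM KCl epoch.
#' @param n_frames Total number of frames in the recording.
#'
#' @return An object of class `acq_timeline`.
#' @seealso [default_timeline()] for the stock epoch layout.
#' @export
acquisition_timeline <- function(frame_period_s, baseline_window, compound_frame,
                                 wash_window, kcl_window, n_frames) {
  stopifnot(is.numeric(frame_period_s), length(frame_period_s) == 1L)
  if (frame_period_s <= 0) abort("`frame_period_s` must be > 0.")
  win_ok <- function(w) length(w) == 2L && all(w == as.integer(w)) && w[1] <= w[2]
  if (!win_ok(baseline_window) || !win_ok(wash_window) || !win_ok(kcl_window)) {
    abort("Windows must be integer intervals c(first, last) with first <= last.")
  }
  compound_frame <- as.integer(compound_frame)
  if (!(baseline_window[2] < compound_frame &&
        compound_frame <= wash_window[1] &&
        wash_window[2] < kcl_window[1])) {
    abort("Epochs must be ordered: baseline < compound <= wash < kcl.")
  }
  if (kcl_window[2] > n_frames || baseline_window[1] < 1) {
    abort("Window indices must lie within 1..n_frames.")
  }
  structure(
    list(
      frame_period_s = as.numeric(frame_period_s),
      baseline_window = as.integer(baseline_window),
      compound_frame = compound_frame,
      wash_window = as.integer(wash_window),
      kcl_window = as.integer(kcl_window),
      n_frames = as.integer(n_frames)
    ),
    class = "acq_timeline"
  )
}

#' Default epoch layout
#'
#' Baseline 120 s, compound 300 s, wash 120 s, KCl 60 s at a 1.5 s frame
#' period (so 80 frames span about two minutes). The drug epoch runs from
#' `compound_frame` to the frame before the wash window.
#'
#' @param frame_period_s Frame period in seconds (default 1.5).
#' @param baseline_s,compound_s,wash_s,kcl_s Epoch durations in seconds.
#' @return An `acq_timeline`.
#' @export
default_timeline <- function(frame_period_s = 1.5, baseline_s = 120,
                             compound_s = 300, wash_s = 120, kcl_s = 60) {
  nb <- max(1L, round(baseline_s / frame_period_s))
  nc <- max(1L, round(compound_s / frame_period_s))
  nw <- max(1L, round(wash_s / frame_period_s))
  nk <- max(1L, round(kcl_s / frame_period_s))
  acquisition_timeline(
    frame_period_s = frame_period_s,
    baseline_window = c(1L, nb),
    compound_frame = nb + 1L,
    wash_window = c(nb + nc + 1L, nb + nc + nw),
    kcl_window = c(nb + nc + nw + 1L, nb + nc + nw + nk),
    n_frames = nb + nc + nw + nk
  )
}

#' Drug-epoch frames of a timeline
#'
#' @param timeline An `acq_timeline`.
#' @return Integer vector of frame indices from compound application to the
#'   frame before the wash window.
#' @export
drug_window <- function(timeline) {
  seq.int(timeline$compound_frame, timeline$wash_window[1] - 1L)
}

#' @export
print.acq_timeline <- function(x, ...) {
  cat("<acq_timeline> ", x$n_frames, " frames @ ", x$frame_period_s, " s\n",
      "  baseline ", x$baseline_window[1], "-", x$baseline_window[2],
      " | drug ", x$compound_frame, "-", x$wash_window[1] - 1L,
      " | wash ", x$wash_window[1], "-", x$wash_window[2],
      " | KCl ", x$kcl_window[1], "-", x$kcl_window[2], "\n", sep = "")
  invisible(x)
}

#' Write / read a timeline as a JSON sidecar
#'
#' @param timeline An `acq_timeline`.
#' @param path File path.
#' @return `write_timeline()` returns `path` invisibly; `read_timeline()`
#'   returns an `acq_timeline`.
#' @export
write_timeline <- function(timeline, path) {
  jsonlite::write_json(unclass(timeline), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_timeline(
    frame_period_s = x$frame_period_s,
    baseline_window = x$baseline_window,
    compound_frame = x$compound_frame,
    wash_window = x$wash_window,
    kcl_window = x$kcl_window,
    n_frames = x$n_frames
  )
}
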