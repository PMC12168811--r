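#' Read and write long-format trace tables
#'
#' The on-disk format is a CSV with columns `roi_id`, `frame`, `raw_f`
#' (column name `raw_F` is accepted on read).
#'
#' @param path CSV file path.
#' @param traces Trace tibble.
#' @return `read_trace_csv()` returns a tibble; `write_trace_csv()` returns
#'   `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "raw_F"] <- "raw_f"
  if (!all(c("roi_id", "frame", "raw_f") %in% names(df))) {
    abort("Trace CSV needs columns roi_id, frame, raw_f.")
  }
  as_tibble(df)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a numeric array
#'
#' Pages become the third array dimension (frames of a movie, or channels
#' of a projected multi-channel image).
#'
#' @param path TIFF file path.
#' @param as_integer_labels Round to integers (for label masks).
#' @return Numeric array `h x w x pages` (or `h x w` for one page).
#' @export
read_tiff_stack <- function(path, as_integer_labels = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_integer_labels)
  arr <- simplify2array(pages)
  if (as_integer_labels) arr <- round(arr)
  arr
}

#' Write a numeric array as a multi-page TIFF
#'
#' Values are rescaled to `[0, 1]` by `max_value` before writing; a JSON
#' sidecar (same path plus `.json`) stores the pixel size so it survives
#' round-tripping.
#'
#' @param arr Array `h x w x pages` or matrix.
#' @param path Output TIFF path.
#' @param pixel_size_um Optional pixel size recorded in the sidecar.
#' @param max_value Intensity ceiling used for scaling (default the array
#'   maximum).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(arr, path, pixel_size_um = NULL, max_value = NULL) {
  mx <- max_value %||% max(arr)
  if (mx <= 0) mx <- 1
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  pages <- lapply(seq_len(dim(arr)[3]), function(k) pmin(pmax(arr[, , k] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(pixel_size_um)) {
    jsonlite::write_json(list(pixel_size_um = pixel_size_um, max_value = mx),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a sweep recording as text files
#'
#' Sweeps go to `<stem>_sweeps.csv` (one column per amplitude), the
#' protocol and metadata to `<stem>_protocol.json`, and the gap-free
#' segment (when present) to `<stem>_gapfree.csv`.
#'
#' @param recording A [sweep_recording()].
#' @param stem Path stem (no extension).
#' @return `write_sweep_recording()` returns `stem` invisibly;
#'   `read_sweep_recording()` returns a [sweep_recording()].
#' @export
write_sweep_recording <- function(recording, stem) {
  sw <- as.data.frame(recording$sweeps)
  names(sw) <- paste0("pA_", recording$amplitudes_pA)
  utils::write.csv(sw, paste0(stem, "_sweeps.csv"), row.names = FALSE)
  meta <- recording[c("amplitudes_pA", "sampling_rate_Hz", "step_start_s",
                      "step_duration_s", "ljp_mV", "holding_mode",
                      "ljp_applied")]
  jsonlite::write_json(meta, paste0(stem, "_protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(recording$gapfree)) {
    utils::write.csv(data.frame(vm_mV = recording$gapfree),
                     paste0(stem, "_gapfree.csv"), row.names = FALSE)
  }
  invisible(stem)
}

#' @rdname write_sweep_recording
#' @export
read_sweep_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_protocol.json"),
                              simplifyVector = TRUE)
  sw <- as.matrix(utils::read.csv(paste0(stem, "_sweeps.csv")))
  gf_path <- paste0(stem, "_gapfree.csv")
  gapfree <- if (file.exists(gf_path)) utils::read.csv(gf_path)$vm_mV else NULL
  rec <- sweep_recording(
    sweeps = unname(sw), amplitudes_pA = meta$amplitudes_pA,
    sampling_rate_Hz = meta$sampling_rate_Hz,
    step_start_s = meta$step_start_s, step_duration_s = meta$step_duration_s,
    ljp_mV = meta$ljp_mV, holding_mode = meta$holding_mode, gapfree = gapfree
  )
  rec$ljp_applied <- isTRUE(meta$ljp_applied)
  rec
}
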