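#' Configuration of a synthetic calcium-imaging cohort
#'
#' Describes a cohort of per-ROI fluorescence traces with known ground truth:
#' a fraction of dead cells (no KCl transient), and among live cells a
#' fraction of drug responders whose transients exceed every responder
#' criterion by `response_margin`, so the truth labels are unambiguous.
#'
#' @param n_cells Number of ROIs (> 0).
#' @param frac_dead Fraction of dead cells in `[0, 1]`.
#' @param frac_responders_among_live Fraction of live cells that respond to
#'   the compound, in `[0, 1]`.
#' @param archetype_mix Named weights over the four transient archetypes
#'   `slow`, `intermediate`, `rapid`, `oscillatory`; must sum to 1.
#' @param amplitude Peak dF/F of responder transients (default 0.5).
#' @param noise_sd Gaussian noise SD in dF/F units (default 0.02).
#' @param frame_period_s Frame period, seconds (default 1.5, so 80 frames
#'   span about two minutes).
#' @param epoch_durations_s Named list of epoch durations in seconds
#'   (`baseline`, `compound`, `wash`, `kcl`).
#' @param response_margin Multiplier >= 1 applied to every classification
#'   threshold when constructing responders (frame counts scaled up, onset
#'   window scaled down, amplitudes scaled up), default 1.5.
#' @param seed Integer seed.
#' @return A list of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_cells = 100L, frac_dead = 0.1,
                               frac_responders_among_live = 0.4,
                               archetype_mix = c(slow = 0.25, intermediate = 0.25,
                                                 rapid = 0.25, oscillatory = 0.25),
                               amplitude = 0.5, noise_sd = 0.02,
                               frame_period_s = 1.5,
                               epoch_durations_s = list(baseline = 120, compound = 300,
                                                        wash = 120, kcl = 60),
                               response_margin = 1.5, seed = 1L) {
  if (n_cells < 1) abort("Empty cohort: `n_cells` must be >= 1.")
  if (frac_dead < 0 || frac_dead > 1 ||
      frac_responders_among_live < 0 || frac_responders_among_live > 1) {
    abort("Fractions must lie in [0, 1].")
  }
  kinds <- c("slow", "intermediate", "rapid", "oscillatory")
  if (!setequal(names(archetype_mix), kinds)) {
    abort("`archetype_mix` must be named over slow/intermediate/rapid/oscillatory.")
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) abort("Archetype weights must sum to 1.")
  if (frame_period_s <= 0) abort("`frame_period_s` must be > 0.")
  if (response_margin < 1) abort("`response_margin` must be >= 1.")
  if (noise_sd < 0 || amplitude <= 0) abort("Need noise_sd >= 0 and amplitude > 0.")
  structure(
    list(
      n_cells = as.integer(n_cells), frac_dead = frac_dead,
      frac_responders_among_live = frac_responders_among_live,
      archetype_mix = archetype_mix[kinds], amplitude = amplitude,
      noise_sd = noise_sd, frame_period_s = frame_period_s,
      epoch_durations_s = epoch_durations_s,
      response_margin = response_margin, seed = as.integer(seed)
    ),
    class = "calcium_sim_config"
  )
}

#' Generate one transient archetype
#'
#' Returns the noise-free dF/F signal of a single transient placed at
#' `onset_frame`, over the whole trace length. The monophasic archetypes rise
#' linearly over two frames to exactly `amplitude`, then decay exponentially
#' with time constants ordered slow (60 s) > intermediate (20 s) > rapid
#' (5 s). The oscillatory archetype is a raised-cosine train (period 15 s)
#' peaking at `amplitude` on every cycle, running to the end of the drug
#' epoch.
#'
#' @param archetype One of `"slow"`, `"intermediate"`, `"rapid"`,
#'   `"oscillatory"`.
#' @param amplitude Peak dF/F (> 0).
#' @param onset_frame Frame at which the transient starts.
#' @param timeline An `acq_timeline`.
#' @return Numeric vector of length `timeline$n_frames`.
#' @export
gen_transient <- function(archetype, amplitude, onset_frame, timeline) {
  kinds <- c(slow = 60, intermediate = 20, rapid = 5)
  if (!archetype %in% c(names(kinds), "oscillatory")) {
    abort(paste0("Unknown archetype: '", archetype, "'."))
  }
  if (amplitude <= 0) abort("`amplitude` must be > 0.")
  n <- timeline$n_frames
  fp <- timeline$frame_period_s
  sig <- numeric(n)
  if (onset_frame > n) return(sig)
  if (archetype == "oscillatory") {
    last <- drug_window(timeline)[length(drug_window(timeline))]
    idx <- seq.int(onset_frame, min(last, n))
    t_rel <- (idx - onset_frame) * fp
    sig[idx] <- amplitude * 0.5 * (1 - cos(2 * pi * t_rel / 15))
  } else {
    tau <- kinds[[archetype]]
    rise_frames <- 2L
    peak_frame <- min(onset_frame + rise_frames, n)
    ridx <- seq.int(onset_frame, peak_frame)
    sig[ridx] <- amplitude * (ridx - onset_frame) / rise_frames
    if (peak_frame < n) {
      didx <- seq.int(peak_frame, n)
      sig[didx] <- amplitude * exp(-((didx - peak_frame) * fp) / tau)
    }
  }
  sig
}

#' Generate a synthetic calcium cohort with ground truth
#'
#' Builds per-ROI raw fluorescence traces over a baseline / compound / wash /
#' KCl epoch layout. Live cells carry a sustained KCl-epoch transient that
#' exceeds the live-cell criterion by the configured margin; true responders
#' additionally carry a drug-epoch transient (archetype drawn from the
#' configured mix, riding on a sustained plateau) that exceeds the frame
#' count, onset window, and amplitude criteria by the margin. Dead cells have
#' no KCl transient. Output is bit-identical for a fixed seed.
#'
#' @param config A [calcium_sim_config()].
#' @return A list: `traces` (tibble `roi_id`, `frame`, `raw_f`), `timeline`
#'   (an `acq_timeline`), `truth` (tibble `roi_id`, `class` in
#'   dead/non-responder/responder, `archetype`, `onset_frame`).
#' @export
gen_calcium_cohort <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  set.seed(config$seed)
  ep <- config$epoch_durations_s
  tl <- default_timeline(config$frame_period_s, ep$baseline, ep$compound,
                         ep$wash, ep$kcl)
  n <- config$n_cells
  n_dead <- round(config$frac_dead * n)
  n_live <- n - n_dead
  n_resp <- round(config$frac_responders_among_live * n_live)

  classes <- sample(c(rep("dead", n_dead),
                      rep("responder", n_resp),
                      rep("non-responder", n_live - n_resp)))
  kinds <- names(config$archetype_mix)
  archetypes <- ifelse(
    classes == "responder",
    sample(kinds, n, replace = TRUE, prob = config$archetype_mix),
    NA_character_
  )

  m <- config$response_margin
  params <- responder_params()
  fp <- tl$frame_period_s
  dw <- drug_window(tl)
  # latest onset honouring both the shrunk onset window and the need to fit
  # margin * responder_min_frames suprathreshold frames before the wash
  max_onset_rel <- floor(min(
    params$onset_window_s / m / fp,
    length(dw) - ceiling(m * params$responder_min_frames) - 5L
  ))
  if (max_onset_rel < 2L) abort("Drug epoch too short for the configured margin.")
  onset_rel <- sample.int(max_onset_rel - 1L, n, replace = TRUE) + 1L
  onset_frame <- ifelse(classes == "responder",
                        tl$compound_frame + onset_rel, NA_integer_)

  plateau_h <- m * (params$k_sd * config$noise_sd + params$min_amplitude)
  amp <- max(config$amplitude, m * params$min_amplitude)
  kcl_amp <- max(1, plateau_h)

  f0 <- runif(n, 500, 2000)
  sig <- matrix(0, nrow = n, ncol = tl$n_frames)
  kcl_idx <- seq.int(tl$kcl_window[1], tl$kcl_window[2])
  for (i in seq_len(n)) {
    if (classes[i] != "dead") {
      # sustained KCl depolarisation: 2-frame rise then hold
      rise <- pmin((kcl_idx - tl$kcl_window[1]) / 2, 1)
      sig[i, kcl_idx] <- kcl_amp * rise
    }
    if (classes[i] == "responder") {
      on <- onset_frame[i]
      plat <- seq.int(on, dw[length(dw)])
      ramp <- pmin((plat - on) / 2, 1)
      sig[i, plat] <- plateau_h * ramp
      sig[i, ] <- sig[i, ] + gen_transient(archetypes[i], amp, on, tl)
      # drug response ends with the drug epoch so the wash baseline is clean
      sig[i, seq.int(tl$wash_window[1], tl$wash_window[2])] <- 0
      sig[i, kcl_idx] <- kcl_amp * pmin((kcl_idx - tl$kcl_window[1]) / 2, 1)
    }
  }
  noise <- matrix(rnorm(n * tl$n_frames, sd = config$noise_sd),
                  nrow = n, ncol = tl$n_frames)
  raw <- f0 * (1 + sig + noise)

  traces <- tibble(
    roi_id = rep(seq_len(n), each = tl$n_frames),
    frame = rep(seq_len(tl$n_frames), times = n),
    raw_f = as.vector(t(raw))
  )
  truth <- tibble(
    roi_id = seq_len(n), class = classes,
    archetype = archetypes, onset_frame = as.integer(onset_frame)
  )
  list(traces = traces, timeline = tl, truth = truth)
}
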