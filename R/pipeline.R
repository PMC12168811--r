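
.allowed_keys <- list(
  top = c("seed", "out_dir", "stages", "log_level",
          "calcium", "image", "ephys", "stats"),
  calcium = c("simulate", "traces_csv", "timeline_json", "params"),
  image = c("simulate", "image_tiff", "pixel_size_um"),
  ephys = c("simulate", "recording_stem", "gapfree_s"),
  stats = c("extraction_csv")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0L) {
    abort(paste0("Unknown config key", if (length(bad) > 1) "s", " in ", where,
                 ": ", paste(bad, collapse = ", ")))
  }
}

#' Validate a run configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), rejects unknown
#' keys (so misspellings fail loudly), fills documented defaults, and
#' checks that every referenced input file exists before any computation
#' runs.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("Config must be a file path or a list.")
  .check_keys(config, .allowed_keys$top, "top level")
  stage_names <- intersect(c("calcium", "image", "ephys", "stats"), names(config))
  out <- list(
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% "sensikit_run",
    stages = config$stages %||% stage_names,
    log_level = config$log_level %||% "info"
  )
  bad_stage <- setdiff(out$stages, c("calcium", "image", "ephys", "stats"))
  if (length(bad_stage) > 0L) {
    abort(paste0("Unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  for (st in out$stages) {
    blk <- config[[st]] %||% list()
    .check_keys(blk, .allowed_keys[[st]], paste0("stage '", st, "'"))
    out[[st]] <- blk
  }
  # validation-first: every referenced input must exist before any stage runs
  for (f in c(out$calcium$traces_csv, out$calcium$timeline_json,
              out$image$image_tiff, out$stats$extraction_csv)) {
    if (!is.null(f) && !file.exists(f)) abort(paste0("Missing input file: ", f))
  }
  if (!is.null(out$ephys$recording_stem) &&
      !file.exists(paste0(out$ephys$recording_stem, "_protocol.json"))) {
    abort(paste0("Missing input file: ", out$ephys$recording_stem,
                 "_protocol.json"))
  }
  structure(out, class = "run_config")
}

#' Serialise a run configuration to YAML
#'
#' @param config A `run_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log_stage <- function(level, stage, msg) {
  if (identical(level, "quiet")) return(invisible(NULL))
  message("[", stage, "] ", msg)
}

#' Run a configuration-driven simulate / analyse / summarise pipeline
#'
#' Executes the requested stages in order, writing every analysis product
#' as a text file under `out_dir`, then records a run manifest
#' (`manifest.json`) holding the toolkit version, the normalized config and
#' its checksum, and an MD5 checksum per output file. Two runs with the
#' same config and seed produce byte-identical analysis files; only the
#' manifest timestamps differ.
#'
#' @param config A `run_config` from [validate_config()], a list, or a
#'   config file path.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lv <- config$log_level
  outputs <- character()
  add <- function(path) outputs <<- c(outputs, path)
  seed <- config$seed

  if ("calcium" %in% config$stages) {
    blk <- config$calcium
    prm <- do.call(responder_params, blk$params %||% list())
    if (!is.null(blk$traces_csv)) {
      .log_stage(lv, "calcium", paste0("reading traces from ", blk$traces_csv))
      traces <- read_trace_csv(blk$traces_csv)
      tl <- read_timeline(blk$timeline_json)
    } else {
      .log_stage(lv, "calcium", "simulating cohort")
      sim_cfg <- do.call(calcium_sim_config,
                         modifyList(blk$simulate %||% list(), list(seed = seed)))
      cohort <- gen_calcium_cohort(sim_cfg)
      traces <- cohort$traces
      tl <- cohort$timeline
      add(write_trace_csv(traces, file.path(config$out_dir, "calcium_traces.csv")))
      add(write_timeline(tl, file.path(config$out_dir, "calcium_timeline.json")))
      utils::write.csv(cohort$truth,
                       file.path(config$out_dir, "calcium_truth.csv"),
                       row.names = FALSE)
      add(file.path(config$out_dir, "calcium_truth.csv"))
    }
    calls <- classify_cells(traces, tl, prm)
    utils::write.csv(calls, file.path(config$out_dir, "calcium_calls.csv"),
                     row.names = FALSE)
    add(file.path(config$out_dir, "calcium_calls.csv"))
    utils::write.csv(summarize_coverslip(calls),
                     file.path(config$out_dir, "calcium_summary.csv"),
                     row.names = FALSE)
    add(file.path(config$out_dir, "calcium_summary.csv"))
    .log_stage(lv, "calcium", paste0(nrow(calls), " ROIs classified"))
  }

  if ("image" %in% config$stages) {
    blk <- config$image
    if (!is.null(blk$image_tiff)) {
      .log_stage(lv, "image", paste0("reading image from ", blk$image_tiff))
      img <- read_tiff_stack(blk$image_tiff)
      psz <- blk$pixel_size_um %||% 0.62
    } else {
      .log_stage(lv, "image", "simulating slide")
      sim_cfg <- do.call(image_sim_config,
                         modifyList(blk$simulate %||% list(), list(seed = seed)))
      slide <- gen_if_image(sim_cfg)
      img <- slide$image
      psz <- sim_cfg$pixel_size_um
      utils::write.csv(slide$truth,
                       file.path(config$out_dir, "image_truth.csv"),
                       row.names = FALSE)
      add(file.path(config$out_dir, "image_truth.csv"))
    }
    purity <- compute_purity(img, pixel_size_um = psz)
    jsonlite::write_json(as.list(purity),
                         file.path(config$out_dir, "image_purity.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(config$out_dir, "image_purity.json"))
    .log_stage(lv, "image", paste0("purity ", round(purity$purity_pct, 1), "%"))
  }

  if ("ephys" %in% config$stages) {
    blk <- config$ephys
    if (!is.null(blk$recording_stem)) {
      .log_stage(lv, "ephys", paste0("reading recording ", blk$recording_stem))
      rec <- read_sweep_recording(blk$recording_stem)
    } else {
      .log_stage(lv, "ephys", "simulating recording")
      sim_cfg <- do.call(neuron_sim_config,
                         modifyList(blk$simulate %||% list(), list(seed = seed)))
      sim <- gen_current_clamp(sim_cfg, gapfree_s = blk$gapfree_s %||% 0)
      rec <- sim$recording
      jsonlite::write_json(sim$truth[c("rmp_mV", "rheobase_pA")],
                           file.path(config$out_dir, "ephys_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      add(file.path(config$out_dir, "ephys_truth.json"))
    }
    rec <- correct_ljp(rec)
    feats <- ephys_features(rec)
    fi <- feats$fi[[1]]
    utils::write.csv(select(feats, -"fi"),
                     file.path(config$out_dir, "ephys_features.csv"),
                     row.names = FALSE)
    add(file.path(config$out_dir, "ephys_features.csv"))
    utils::write.csv(fi, file.path(config$out_dir, "ephys_fi.csv"),
                     row.names = FALSE)
    add(file.path(config$out_dir, "ephys_fi.csv"))
    .log_stage(lv, "ephys", paste0("rheobase ", feats$rheobase_pA, " pA"))
  }

  if ("stats" %in% config$stages && !is.null(config$stats$extraction_csv)) {
    .log_stage(lv, "stats", "literature synthesis")
    meta <- literature_meta(read_extraction_csv(config$stats$extraction_csv))
    utils::write.csv(tidy(meta),
                     file.path(config$out_dir, "literature_effects.csv"),
                     row.names = FALSE)
    add(file.path(config$out_dir, "literature_effects.csv"))
    jsonlite::write_json(as.list(glance(meta)),
                         file.path(config$out_dir, "literature_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(config$out_dir, "literature_summary.json"))
  }

  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    toolkit = "sensikit",
    version = as.character(utils::packageVersion("sensikit")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
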