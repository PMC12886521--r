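# Trial stacks are written as 16-bit multi-page TIFF. Rendered frames are
# integer-valued (photon-count-like), so the quantized round trip is exact.
MAX16 <- 65535

sidecar_path <- function(tiff_path) {
  sub("\\.tiff?$", ".meta.txt", tiff_path, ignore.case = TRUE)
}

write_sidecar <- function(path, meta) {
  writeLines(sprintf("%s=%s", names(meta),
                     vapply(meta, format, "", digits = 17)), path)
}

read_sidecar <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(x[2]))
    if (is.na(v)) x[2] else v
  })
  setNames(vals, vapply(kv, `[[`, "", 1))
}

#' Write a trial stack as multi-page TIFF with metadata sidecar
#'
#' Frames are stored as 16-bit pages; a plain-text `key=value` sidecar
#' (`<name>.meta.txt`) records `frame_rate_hz`, `pixel_size_um`,
#' `stim_onset_s`, `stim_duration_s` and `trial_duration_s`. Because rendered
#' frames hold integer intensities, [read_trial_stack()] restores the array
#' bit-identically.
#'
#' @param trial A `synthetic_trial` or [image_stack()].
#' @param path Output `.tif` path.
#' @param protocol A [stim_protocol()] for the sidecar timing fields.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, protocol = stim_protocol()) {
  stack <- if (inherits(trial, "synthetic_trial")) trial$stack else trial
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  if (any(fr < 0) || any(fr != round(fr)) || max(fr) > MAX16) {
    abort("trial frames must be integers in [0, 65535] for 16-bit storage")
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k] / MAX16)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  write_sidecar(sidecar_path(path), list(
    frame_rate_hz = stack$frame_rate_hz,
    pixel_size_um = stack$pixel_size_um,
    stim_onset_s = protocol$stim_onset_s,
    stim_duration_s = protocol$stim_duration_s,
    trial_duration_s = protocol$trial_duration_s
  ))
  invisible(path)
}

#' Read a trial stack from multi-page TIFF
#'
#' Metadata are resolved from the sidecar written by [write_trial()] first;
#' explicit arguments override the sidecar (with a warning on conflict) and
#' are required when no sidecar exists.
#'
#' @param path `.tif` path.
#' @param frame_rate_hz,pixel_size_um Optional overrides.
#' @return An [image_stack()].
#' @export
read_trial_stack <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) abort(sprintf("corrupt or unreadable TIFF %s: %s",
                                                      path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- round(pages[[k]] * MAX16)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- read_sidecar(sp)
  pick <- function(override, key) {
    if (!is.null(override)) {
      if (!is.null(meta[[key]]) && !isTRUE(all.equal(meta[[key]], override))) {
        warn(sprintf("%s: override %s=%g conflicts with sidecar (%g); using override",
                     basename(path), key, override, meta[[key]]))
      }
      override
    } else if (!is.null(meta[[key]])) {
      meta[[key]]
    } else {
      abort(sprintf("%s missing for %s: no sidecar value and no override", key, path))
    }
  }
  image_stack(fr, pick(frame_rate_hz, "frame_rate_hz"),
              pick(pixel_size_um, "pixel_size_um"))
}

#' Write a synthetic session to a directory tree
#'
#' Lays the session out as `group/mouse/pa/timepoint/trial_NN.tif` (with
#' sidecars) plus `ground_truth.csv` at the root — the on-disk layout
#' [run_pipeline()] consumes.
#'
#' @param session A [generate_session()] result with rendered trials.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_session <- function(session, out_dir) {
  stopifnot(inherits(session, "synthetic_session"))
  if (is.null(session$trials)) abort("session has no rendered trials")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  for (g in names(tr)) for (m in names(tr[[g]])) for (p in names(tr[[g]][[m]])) {
    for (tp in names(tr[[g]][[m]][[p]])) {
      d <- file.path(out_dir, g, m, p, tp)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      reps <- tr[[g]][[m]][[p]][[tp]]
      for (k in seq_along(reps)) {
        write_trial(reps[[k]], file.path(d, sprintf("trial_%02d.tif", k)),
                    session$protocol)
      }
    }
  }
  write.csv(session$truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Pipeline configuration
#'
#' Bundles every tunable of a full run: trial protocol, synthetic-session
#' design and noise (when simulating), segmentation parameters, statistics
#' factors, seed and output directory. Round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param protocol A [stim_protocol()].
#' @param design A [session_design()] (used by the simulate stage).
#' @param noise A [noise_model()].
#' @param segmentation Named list: `low_pct`, `high_pct`, `method`,
#'   `threshold`, `angular_step_deg`, `sample_step_px`, `estimator`.
#' @param stats_metric,stats_factors Metric column and factor columns for the
#'   statistics stage.
#' @param frame_dim Rendered frame size.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = stim_protocol(),
                            design = session_design(),
                            noise = noise_model(),
                            segmentation = list(
                              low_pct = 1, high_pct = 99, method = "otsu",
                              threshold = NULL, angular_step_deg = 1,
                              sample_step_px = 0.25, estimator = "ellipse"
                            ),
                            stats_metric = "amplitude_pct",
                            stats_factors = "group",
                            frame_dim = c(96, 96),
                            seed = 1L,
                            out_dir = "lumenpulse_run") {
  structure(
    list(protocol = protocol, design = design, noise = noise,
         segmentation = segmentation, stats_metric = stats_metric,
         stats_factors = stats_factors, frame_dim = frame_dim,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  # named numeric vectors become YAML maps so their names survive the trip
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (!is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(strip(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  # YAML has no distinct scalar-NULL: empty nodes come back as empty lists
  denull <- function(v) if (is.list(v) && length(v) == 0) NULL else v
  num <- function(v) if (is.list(v)) unlist(v) else v
  if (is.list(x$design$timepoint_offsets) &&
      length(x$design$timepoint_offsets) == 0) {
    x$design["timepoint_offsets"] <- list(NULL)
  }
  sg <- x$segmentation
  segmentation <- list(
    low_pct = sg$low_pct, high_pct = sg$high_pct, method = sg$method,
    threshold = denull(sg$threshold),
    angular_step_deg = sg$angular_step_deg,
    sample_step_px = sg$sample_step_px,
    estimator = sg$estimator %||% "ellipse"
  )
  groups <- lapply(x$design$groups, function(g) unlist(g))
  pipeline_config(
    protocol = stim_protocol(
      x$protocol$trial_duration_s, x$protocol$frame_rate_hz,
      x$protocol$stim_onset_s, x$protocol$stim_duration_s,
      x$protocol$basal_window_start_s, x$protocol$n_trials
    ),
    design = session_design(
      n_mice_per_group = x$design$n_mice_per_group,
      pas_per_mouse = num(x$design$pas_per_mouse),
      groups = groups,
      timepoints = num(x$design$timepoints),
      timepoint_offsets = if (is.null(x$design$timepoint_offsets)) NULL else
        lapply(x$design$timepoint_offsets, unlist),
      mean_amplitude_pct = x$design$mean_amplitude_pct,
      mean_t_max_s = x$design$mean_t_max_s,
      sd_mouse_amplitude = x$design$sd_mouse_amplitude,
      sd_pa_amplitude = x$design$sd_pa_amplitude,
      sd_mouse_t_max = x$design$sd_mouse_t_max,
      sd_pa_t_max = x$design$sd_pa_t_max,
      basal_range_um = num(x$design$basal_range_um),
      seed = x$design$seed
    ),
    noise = noise_model(
      x$noise$vessel_intensity, x$noise$background_intensity,
      x$noise$gaussian_sd, x$noise$poisson_scale,
      x$noise$motion_jitter_sd_px, denull(x$noise$seed)
    ),
    segmentation = segmentation,
    stats_metric = x$stats_metric,
    stats_factors = num(x$stats_factors),
    frame_dim = num(x$frame_dim),
    seed = x$seed,
    out_dir = x$out_dir
  )
}

#' Run the full pipeline
#'
#' Ties the stages together: simulate (optional) -> per-trial diameter
#' extraction -> per-arteriole metric computation -> nested group statistics,
#' writing per-trial trace CSVs, the combined metric table, a statistics
#' report and a run manifest under `config$out_dir`. The run is deterministic
#' given the config and seed.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @param simulate If `TRUE`, generate and write a synthetic session into
#'   `out_dir/raw` first; otherwise `out_dir/raw` must already hold the
#'   `group/mouse/pa/timepoint/trial_NN.tif` layout.
#' @return A list of class `run_manifest`: config hash, seed, package
#'   version, timestamps, stage file listings, and the metric table.
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  raw <- file.path(out, "raw")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (simulate) {
    design <- config$design
    design$seed <- config$seed
    session <- generate_session(design, config$protocol, config$noise,
                                render = TRUE, frame_dim = config$frame_dim)
    write_session(session, raw)
  }
  if (!dir.exists(raw)) abort("simulate stage: no raw trial directory found")

  trace_dir <- file.path(out, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  tiffs <- list.files(raw, pattern = "\\.tif$", recursive = TRUE,
                      full.names = TRUE)
  if (length(tiffs) == 0) abort("extract stage: no trial TIFFs found")
  seg <- config$segmentation

  rows <- list()
  # group trials by arteriole-timepoint directory
  by_dir <- split(tiffs, dirname(tiffs))
  for (d in names(by_dir)) {
    rel <- strsplit(sub(paste0("^", raw, "/?"), "", d), "/")[[1]]
    if (length(rel) != 4) abort(sprintf("extract stage: unexpected layout at %s", d))
    traces <- list()
    for (f in sort(by_dir[[d]])) {
      stack <- tryCatch(read_trial_stack(f),
                        error = function(e) abort(sprintf("extract stage failed on %s: %s",
                                                          f, conditionMessage(e))))
      tr <- extract_diameter_trace(
        stack, seg$low_pct, seg$high_pct, seg$method, seg$threshold,
        seg$angular_step_deg, seg$sample_step_px,
        seg$estimator %||% "ellipse"
      )
      csv <- file.path(trace_dir, paste0(paste(rel, collapse = "_"), "_",
                                         sub("\\.tif$", ".csv", basename(f))))
      write.csv(tr, csv, row.names = FALSE)
      traces[[length(traces) + 1]] <- normalize_trace(tr, config$protocol)
    }
    met <- compute_metrics(average_trials(traces))
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(group = rel[1], mouse_id = rel[2], pa_id = rel[3],
             timepoint = rel[4]),
      met
    )
  }
  metric_table <- dplyr::arrange(dplyr::bind_rows(rows),
                                 .data$group, .data$mouse_id, .data$pa_id,
                                 .data$timepoint)
  mt_path <- file.path(out, "metric_table.csv")
  write.csv(metric_table, mt_path, row.names = FALSE)

  stats_res <- nested_compare(metric_table, config$stats_metric,
                              config$stats_factors)
  stats_path <- file.path(out, "stats_report.txt")
  withr_local <- file(stats_path, "w")
  sink(withr_local); print(stats_res); sink()
  close(withr_local)
  write.csv(tidy(stats_res), file.path(out, "stats_pairwise.csv"),
            row.names = FALSE)

  files <- list.files(out, recursive = TRUE)
  manifest <- structure(
    list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      version = as.character(utils::packageVersion("lumenpulse")),
      started = format(t0), finished = format(Sys.time()),
      files = files,
      metric_table = metric_table,
      stats = stats_res
    ),
    class = "run_manifest"
  )
  yaml::write_yaml(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         version = manifest$version, started = manifest$started,
         finished = manifest$finished, files = files),
    file.path(out, "manifest.yaml")
  )
  manifest
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d files, config %s\n",
              x$seed, length(x$files), substr(x$config_hash, 1, 8)))
  invisible(x)
}
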