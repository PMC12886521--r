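#' Ground-truth description of a synthetic vessel
#'
#' Parameters of one simulated penetrating-arteriole cross-section: its resting
#' (basal) lumen diameter, the stimulus-evoked dilation it undergoes, and its
#' geometry in the imaging plane. The dilation is isotropic — major and minor
#' axes scale by the same factor — so the true "diameter" recovered by a
#' minimum-chord measurement is the minor axis at every frame.
#'
#' @param basal_diameter_um Resting lumen diameter (minor axis), micrometres.
#' @param dilation_amplitude_pct Peak dilation as percent of basal (15 means
#'   the diameter peaks at 1.15 x basal). Must exceed -100.
#' @param t_max_s Time from stimulus onset to peak dilation, seconds.
#' @param rise_shape Kinetic form of the rise to peak: `"linear"` (ramp) or
#'   `"gamma"` (gamma-variate-like, concave-up onset).
#' @param gamma_shape Shape exponent of the gamma-like rise (ignored for
#'   `"linear"`).
#' @param decay_tau_s Time constant of the exponential return toward basal
#'   after the peak, seconds.
#' @param ellipticity Major/minor axis ratio of the cross-section (>= 1; 1 is
#'   a circle, i.e. a vessel cut exactly perpendicular to its axis).
#' @param orientation_deg Major-axis orientation in degrees, measured
#'   counter-clockwise from the column axis.
#' @param center_rc Vessel center as `c(row, col)` in pixels (0-based, pixel
#'   centers at integer coordinates).
#' @param pixel_size_um Pixel size, micrometres per pixel (0.5 um/px is a
#'   typical two-photon cross-section zoom).
#'
#' @return An object of class `vessel_truth`.
#' @seealso [diameter_timecourse()], [render_trial()]
#' @export
vessel_truth <- function(basal_diameter_um = 20,
                         dilation_amplitude_pct = 15,
                         t_max_s = 2.5,
                         rise_shape = c("linear", "gamma"),
                         gamma_shape = 2,
                         decay_tau_s = 2,
                         ellipticity = 1.15,
                         orientation_deg = 0,
                         center_rc = c(35.5, 35.5),
                         pixel_size_um = 0.5) {
  rise_shape <- match.arg(rise_shape)
  stopifnot(
    basal_diameter_um > 0,
    dilation_amplitude_pct > -100,
    t_max_s > 0,
    decay_tau_s > 0,
    ellipticity >= 1,
    pixel_size_um > 0,
    length(center_rc) == 2
  )
  structure(
    list(
      basal_diameter_um = basal_diameter_um,
      dilation_amplitude_pct = dilation_amplitude_pct,
      t_max_s = t_max_s,
      rise_shape = rise_shape,
      gamma_shape = gamma_shape,
      decay_tau_s = decay_tau_s,
      ellipticity = ellipticity,
      orientation_deg = orientation_deg,
      center_rc = as.numeric(center_rc),
      pixel_size_um = pixel_size_um
    ),
    class = "vessel_truth"
  )
}

#' Imaging noise and motion model for synthetic trials
#'
#' Emulates the dominant artifacts of awake two-photon imaging: photon shot
#' noise, detector read noise, and frame-to-frame rigid translation of the
#' field of view. Rendered frames are quantized to non-negative integer
#' intensities, as a photon-counting acquisition produces.
#'
#' @param vessel_intensity Mean intensity of the dye-filled lumen (arbitrary
#'   units); must exceed `background_intensity`.
#' @param background_intensity Mean intensity outside the vessel.
#' @param gaussian_sd SD of additive Gaussian (read) noise; 0 disables.
#' @param poisson_scale Photons per intensity unit for shot noise; 0 disables.
#' @param motion_jitter_sd_px SD of the per-frame rigid translation, pixels.
#' @param seed Optional integer seed used when the trial is rendered.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(vessel_intensity = 1000,
                        background_intensity = 100,
                        gaussian_sd = 0,
                        poisson_scale = 0,
                        motion_jitter_sd_px = 0,
                        seed = NULL) {
  stopifnot(
    vessel_intensity > background_intensity,
    gaussian_sd >= 0,
    poisson_scale >= 0,
    motion_jitter_sd_px >= 0
  )
  structure(
    list(
      vessel_intensity = vessel_intensity,
      background_intensity = background_intensity,
      gaussian_sd = gaussian_sd,
      poisson_scale = poisson_scale,
      motion_jitter_sd_px = motion_jitter_sd_px,
      seed = seed
    ),
    class = "noise_model"
  )
}

#' True per-frame diameter time course of a synthetic dilation
#'
#' Builds the dilation kinetics the rendered movie realizes and the recovery
#' tests measure against: constant basal diameter before stimulus onset, a
#' rise to `basal x (1 + amplitude/100)` peaking at the frame nearest
#' `onset + t_max_s`, and an exponential return toward basal afterwards. The
#' peak time is snapped to the frame grid so the peak value is attained
#' exactly at one frame.
#'
#' @param truth A [vessel_truth()].
#' @param protocol A [stim_protocol()].
#' @return Numeric vector of per-frame diameters in micrometres, length
#'   `protocol$n_frames`.
#' @examples
#' tr <- diameter_timecourse(vessel_truth(20, 15, 2.5), stim_protocol())
#' max(tr)  # 23
#' @export
diameter_timecourse <- function(truth, protocol) {
  stopifnot(inherits(truth, "vessel_truth"), inherits(protocol, "stim_protocol"))
  if (truth$t_max_s + protocol$stim_onset_s > protocol$trial_duration_s) {
    abort("t_max_s places the peak beyond the end of the trial")
  }
  t <- frame_times(protocol)
  onset <- protocol$stim_onset_s
  basal <- truth$basal_diameter_um
  peak <- basal * (1 + truth$dilation_amplitude_pct / 100)
  t_peak <- t[which.min(abs(t - (onset + truth$t_max_s)))]

  out <- rep(basal, length(t))
  rise <- t >= onset & t <= t_peak
  if (t_peak > onset) {
    s <- (t[rise] - onset) / (t_peak - onset)
    f <- switch(truth$rise_shape,
      linear = s,
      gamma = s^truth$gamma_shape *
        exp(truth$gamma_shape * (1 - s))
    )
    out[rise] <- basal + (peak - basal) * f
  } else {
    out[t == t_peak] <- peak
  }
  fall <- t > t_peak
  out[fall] <- basal + (peak - basal) * exp(-(t[fall] - t_peak) / truth$decay_tau_s)
  out
}

#' A T x H x W image stack with imaging metadata
#'
#' The raw input of the measurement pipeline: one trial's movie, stored as an
#' `H x W x T` numeric array (frame `t` is `frames[, , t]`), with the frame
#' rate and pixel size needed to convert to physical units.
#'
#' @param frames `H x W x T` numeric array.
#' @param frame_rate_hz Frames per second.
#' @param pixel_size_um Micrometres per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_rate_hz, pixel_size_um) {
  stopifnot(length(dim(frames)) == 3, frame_rate_hz > 0, pixel_size_um > 0)
  if (dim(frames)[3] < 2) abort("an image stack needs at least 2 frames")
  if (any(dim(frames)[1:2] < 8)) abort("frames must be at least 8 x 8 pixels")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "image_stack"
  )
}

#' @exportS3Method base::print
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px @ %g Hz, %g um/px\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' Render one synthetic stimulation trial
#'
#' Rasterizes the vessel cross-section frame by frame as a filled,
#' anti-aliased (area-coverage) ellipse whose minor axis follows the supplied
#' diameter trace, applies per-frame rigid translation jitter, and adds shot
#' and read noise. Frames are quantized to non-negative integers after noise.
#'
#' @param trace Per-frame true minimum diameter in micrometres, typically from
#'   [diameter_timecourse()].
#' @param truth The [vessel_truth()] describing geometry and pixel size.
#' @param noise A [noise_model()].
#' @param protocol A [stim_protocol()]; `length(trace)` must equal its frame
#'   count.
#' @param frame_dim Frame size `c(H, W)` in pixels.
#' @param seed Integer seed for jitter and noise; overrides `noise$seed`.
#'
#' @return An object of class `synthetic_trial`: a list with `stack` (an
#'   [image_stack()]), `truth_trace` (the input trace) and `truth`.
#' @details The configured geometry must keep the ellipse inside the frame
#'   with room for jitter: the maximal semi-major axis plus a 4 SD jitter
#'   margin must fit on every side, otherwise a geometry error is raised.
#'   Drawn jitter is clamped to 4 SD so the guarantee is deterministic.
#' @export
render_trial <- function(trace, truth, noise = noise_model(),
                         protocol = stim_protocol(),
                         frame_dim = c(72, 72), seed = NULL) {
  stopifnot(inherits(truth, "vessel_truth"), inherits(noise, "noise_model"))
  if (length(trace) != protocol$n_frames) {
    abort("trace length does not match the protocol frame count")
  }
  H <- frame_dim[1]; W <- frame_dim[2]
  semi_minor <- trace / truth$pixel_size_um / 2
  semi_major <- semi_minor * truth$ellipticity
  jmax <- 4 * noise$motion_jitter_sd_px
  margin <- max(semi_major) + jmax + 0.5
  ctr <- truth$center_rc
  if (ctr[1] - margin < 0 || ctr[1] + margin > H - 1 ||
      ctr[2] - margin < 0 || ctr[2] + margin > W - 1) {
    abort(sprintf(
      "geometry error: ellipse (semi-major %.1f px + jitter margin %.1f px) does not fit a %d x %d frame at center (%.1f, %.1f)",
      max(semi_major), jmax, H, W, ctr[1], ctr[2]
    ))
  }
  seed <- seed %||% noise$seed
  if (!is.null(seed)) set.seed(seed)
  nT <- length(trace)
  jit <- matrix(0, nT, 2)
  if (noise$motion_jitter_sd_px > 0) {
    jit <- matrix(rnorm(2 * nT, 0, noise$motion_jitter_sd_px), nT, 2)
    jit[jit > jmax] <- jmax
    jit[jit < -jmax] <- -jmax
  }
  frames <- array(0, dim = c(H, W, nT))
  contrast <- noise$vessel_intensity - noise$background_intensity
  for (k in seq_len(nT)) {
    cov <- ellipse_coverage_cpp(
      H, W, ctr[1] + jit[k, 1], ctr[2] + jit[k, 2],
      semi_minor[k], semi_major[k], truth$orientation_deg, 8L
    )
    img <- noise$background_intensity + contrast * cov
    if (noise$poisson_scale > 0) {
      img <- rpois(length(img), img * noise$poisson_scale) / noise$poisson_scale
      dim(img) <- c(H, W)
    }
    if (noise$gaussian_sd > 0) {
      img <- img + rnorm(length(img), 0, noise$gaussian_sd)
    }
    frames[, , k] <- pmax(round(img), 0)
  }
  structure(
    list(
      stack = image_stack(frames, protocol$frame_rate_hz, truth$pixel_size_um),
      truth_trace = trace,
      truth = truth
    ),
    class = "synthetic_trial"
  )
}

#' Design of a hierarchical imaging session
#'
#' Describes the mice -> penetrating arterioles -> timepoints structure of a
#' study arm, with group-level effect offsets and the variance components of
#' the two-level (mouse, arteriole-within-mouse) hierarchy. Used by
#' [generate_session()] to draw per-arteriole ground truths.
#'
#' @param n_mice_per_group Mice per group.
#' @param pas_per_mouse Range `c(min, max)` of arterioles per mouse; must lie
#'   within `[2, 6]`. The count is drawn uniformly per mouse.
#' @param groups Named list of per-group effect offsets, each a numeric vector
#'   with elements `amplitude_pct` and `t_max_s` added to the population
#'   means.
#' @param timepoints Character vector of timepoint labels. Imaging is
#'   longitudinal: the same arterioles are revisited at every timepoint.
#' @param timepoint_offsets Optional named list (by timepoint) of offsets with
#'   the same structure as `groups`; defaults to no timepoint effect.
#' @param mean_amplitude_pct,mean_t_max_s Population means of the dilation
#'   amplitude (percent of basal) and time to peak (s).
#' @param sd_mouse_amplitude,sd_pa_amplitude Between-mouse and
#'   within-mouse (between-arteriole) SDs of the amplitude.
#' @param sd_mouse_t_max,sd_pa_t_max Same, for the time to peak.
#' @param basal_range_um Range of basal diameters; drawn uniformly per
#'   arteriole.
#' @param seed Integer seed; one global seed expands deterministically into
#'   per-trial substreams.
#'
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_mice_per_group = 8,
                           pas_per_mouse = c(2, 6),
                           groups = list(
                             control = c(amplitude_pct = 0, t_max_s = 0),
                             treated = c(amplitude_pct = 0, t_max_s = 0)
                           ),
                           timepoints = "BL",
                           timepoint_offsets = NULL,
                           mean_amplitude_pct = 15,
                           mean_t_max_s = 2.5,
                           sd_mouse_amplitude = 3,
                           sd_pa_amplitude = 3,
                           sd_mouse_t_max = 0.4,
                           sd_pa_t_max = 0.4,
                           basal_range_um = c(15, 30),
                           seed = 1L) {
  stopifnot(
    n_mice_per_group >= 1,
    length(pas_per_mouse) == 2,
    pas_per_mouse[1] >= 2, pas_per_mouse[2] <= 6,
    pas_per_mouse[1] <= pas_per_mouse[2],
    length(groups) >= 1, !is.null(names(groups)),
    sd_mouse_amplitude >= 0, sd_pa_amplitude >= 0,
    sd_mouse_t_max >= 0, sd_pa_t_max >= 0
  )
  structure(
    list(
      n_mice_per_group = as.integer(n_mice_per_group),
      pas_per_mouse = as.integer(pas_per_mouse),
      groups = groups,
      timepoints = timepoints,
      timepoint_offsets = timepoint_offsets,
      mean_amplitude_pct = mean_amplitude_pct,
      mean_t_max_s = mean_t_max_s,
      sd_mouse_amplitude = sd_mouse_amplitude,
      sd_pa_amplitude = sd_pa_amplitude,
      sd_mouse_t_max = sd_mouse_t_max,
      sd_pa_t_max = sd_pa_t_max,
      basal_range_um = basal_range_um,
      seed = as.integer(seed)
    ),
    class = "session_design"
  )
}

#' Generate a hierarchical synthetic session
#'
#' Draws per-arteriole ground truths around the group means with the design's
#' mouse-level and arteriole-level variance components, and (optionally)
#' renders every stimulation trial as a synthetic movie. Sexes alternate
#' within each group so both are represented.
#'
#' @param design A [session_design()].
#' @param protocol A [stim_protocol()]; `protocol$n_trials` movies are
#'   rendered per arteriole and timepoint.
#' @param noise A [noise_model()].
#' @param render If `FALSE`, only the ground-truth table is produced (fast
#'   path for statistical simulation).
#' @param frame_dim Frame size passed to [render_trial()].
#'
#' @return A list of class `synthetic_session` with `truth`, a tibble of the
#'   generating parameters (one row per arteriole x timepoint: `group`,
#'   `mouse_id`, `sex`, `pa_id`, `timepoint`, `basal_diameter_um`,
#'   `dilation_amplitude_pct`, `t_max_s`), and `trials`, a nested list
#'   `trials[[group]][[mouse]][[pa]][[timepoint]]` of [render_trial()] outputs
#'   (`NULL` when `render = FALSE`).
#' @export
generate_session <- function(design, protocol = stim_protocol(),
                             noise = noise_model(), render = TRUE,
                             frame_dim = c(96, 96)) {
  stopifnot(inherits(design, "session_design"))
  set.seed(design$seed)
  tp_off <- function(tp, what) {
    off <- design$timepoint_offsets[[tp]]
    if (is.null(off)) 0 else unname(off[[what]] %||% 0)
  }
  acc <- list(group = character(), mouse_id = character(), sex = character(),
              pa_id = character(), timepoint = character(),
              basal_diameter_um = numeric(),
              dilation_amplitude_pct = numeric(), t_max_s = numeric())
  trials <- list()
  for (g in names(design$groups)) {
    goff <- design$groups[[g]]
    for (m in seq_len(design$n_mice_per_group)) {
      mouse_id <- sprintf("%s_m%02d", g, m)
      sex <- if (m %% 2 == 1) "male" else "female"
      pa_choices <- seq(design$pas_per_mouse[1], design$pas_per_mouse[2])
      n_pa <- pa_choices[sample.int(length(pa_choices), 1)]
      mouse_amp <- rnorm(1, 0, design$sd_mouse_amplitude)
      mouse_tmax <- rnorm(1, 0, design$sd_mouse_t_max)
      for (p in seq_len(n_pa)) {
        pa_id <- sprintf("%s_pa%d", mouse_id, p)
        basal <- runif(1, design$basal_range_um[1], design$basal_range_um[2])
        for (tp in design$timepoints) {
          amp <- design$mean_amplitude_pct + unname(goff[["amplitude_pct"]]) +
            tp_off(tp, "amplitude_pct") + mouse_amp +
            rnorm(1, 0, design$sd_pa_amplitude)
          tmax <- design$mean_t_max_s + unname(goff[["t_max_s"]]) +
            tp_off(tp, "t_max_s") + mouse_tmax +
            rnorm(1, 0, design$sd_pa_t_max)
          tmax <- min(max(tmax, 0.3), protocol$stim_duration_s - 0.1)
          i <- length(acc$group) + 1L
          acc$group[i] <- g; acc$mouse_id[i] <- mouse_id
          acc$sex[i] <- sex; acc$pa_id[i] <- pa_id; acc$timepoint[i] <- tp
          acc$basal_diameter_um[i] <- basal
          acc$dilation_amplitude_pct[i] <- amp
          acc$t_max_s[i] <- tmax
        }
      }
    }
  }
  truth_tbl <- as_tibble(acc)
  if (render) {
    seeds <- sample.int(.Machine$integer.max,
                        nrow(truth_tbl) * protocol$n_trials)
    i <- 0L
    for (r in seq_len(nrow(truth_tbl))) {
      tr <- truth_tbl[r, ]
      vt <- vessel_truth(
        basal_diameter_um = tr$basal_diameter_um,
        dilation_amplitude_pct = tr$dilation_amplitude_pct,
        t_max_s = tr$t_max_s,
        center_rc = (frame_dim - 1) / 2
      )
      trace <- diameter_timecourse(vt, protocol)
      reps <- lapply(seq_len(protocol$n_trials), function(k) {
        i <<- i + 1L
        render_trial(trace, vt, noise, protocol, frame_dim, seed = seeds[i])
      })
      trials[[tr$group]][[tr$mouse_id]][[tr$pa_id]][[tr$timepoint]] <- reps
    }
  }
  structure(list(truth = truth_tbl, trials = if (render) trials else NULL,
                 design = design, protocol = protocol, noise = noise),
            class = "synthetic_session")
}

#' Insulin dose for an insulin-induced hypoglycemia episode
#'
#' Protocol utility implementing the dosing rule used to hold blood glucose in
#' the mild-to-moderate hypoglycemic range:
#' `dose (UI) = 0.75 x body weight (kg) x fasting glucose (mg/dL) / 100`,
#' with a flag raised when the per-kilogram dose falls outside the 1-4 UI/kg
#' administration range.
#'
#' @param body_weight_kg Body weight(s) in kilograms; non-negative.
#' @param fasting_glucose_mg_dl Fasting blood glucose in mg/dL; non-negative.
#' @return A tibble with columns `body_weight_kg`, `fasting_glucose_mg_dl`,
#'   `dose_ui`, `dose_per_kg_ui` (`NA` at zero weight) and `in_range`.
#' @examples
#' insulin_dose(0.025, 400)  # 0.075 UI, 3 UI/kg, in range
#' @export
insulin_dose <- function(body_weight_kg, fasting_glucose_mg_dl) {
  if (any(body_weight_kg < 0) || any(fasting_glucose_mg_dl < 0)) {
    abort("body weight and fasting glucose must be non-negative")
  }
  dose <- 0.75 * body_weight_kg * fasting_glucose_mg_dl / 100
  per_kg <- ifelse(body_weight_kg > 0, dose / body_weight_kg, NA_real_)
  tibble(
    body_weight_kg = body_weight_kg,
    fasting_glucose_mg_dl = fasting_glucose_mg_dl,
    dose_ui = dose,
    dose_per_kg_ui = per_kg,
    in_range = !is.na(per_kg) & per_kg >= 1 & per_kg <= 4
  )
}

#' Simulate an intrinsic optical signal session
#'
#' Generates repeated reflectance trials in which whisker stimulation evokes a
#' focal reflectance decrease (increased light absorption) with a Gaussian
#' spatial profile, on top of independent per-pixel noise — the structure
#' [ios_activity_map()] is designed to recover.
#'
#' @param n_trials Number of stimulation trials (30 in the mapping protocol
#'   this emulates).
#' @param dim Frame size `c(H, W)`.
#' @param n_baseline,n_response Frames in the pre-stimulus baseline and the
#'   stimulation/response window of each trial.
#' @param baseline_intensity Mean reflectance level.
#' @param blob_center_rc True response center, `c(row, col)`, 0-based.
#' @param blob_sigma_px Gaussian SD of the response's spatial profile.
#' @param blob_dr_r Peak fractional reflectance change at the center
#'   (negative for absorption).
#' @param noise_sd Per-pixel, per-frame Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list of class `ios_session`: `trials` (list of `H x W x T`
#'   arrays), `baseline_frames`, `response_frames`, and `truth` (center and
#'   peak response).
#' @export
simulate_ios_session <- function(n_trials = 30, dim = c(64, 64),
                                 n_baseline = 10, n_response = 12,
                                 baseline_intensity = 100,
                                 blob_center_rc = c(31.5, 31.5),
                                 blob_sigma_px = 6,
                                 blob_dr_r = -0.02,
                                 noise_sd = 1,
                                 seed = 1L) {
  set.seed(seed)
  H <- dim[1]; W <- dim[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  blob <- exp(-((rr - blob_center_rc[1])^2 + (cc - blob_center_rc[2])^2) /
                (2 * blob_sigma_px^2))
  nT <- n_baseline + n_response
  trials <- lapply(seq_len(n_trials), function(i) {
    a <- array(baseline_intensity, dim = c(H, W, nT))
    for (k in (n_baseline + 1):nT) {
      a[, , k] <- baseline_intensity * (1 + blob_dr_r * blob)
    }
    a + array(rnorm(H * W * nT, 0, noise_sd), dim = c(H, W, nT))
  })
  structure(
    list(trials = trials,
         baseline_frames = seq_len(n_baseline),
         response_frames = (n_baseline + 1):nT,
         truth = list(center_rc = blob_center_rc, peak_dr_r = blob_dr_r)),
    class = "ios_session"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
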