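#' Percentile-based intensity adjustment of one frame
#'
#' Linearly rescales a frame so that the `low_pct` percentile maps to 0 and
#' the `high_pct` percentile maps to 1, clipping outside. The 1st-99th
#' percentile default is robust to hot pixels and keeps thresholding stable
#' across bleaching or laser-power drift; any global gain applied to the frame
#' cancels exactly.
#'
#' @param frame Numeric matrix.
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return Numeric matrix in `[0, 1]`; a constant frame maps to all zeros.
#' @export
adjust_intensity <- function(frame, low_pct = 1, high_pct = 99) {
  stopifnot(is.matrix(frame), low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  if (length(frame) == 0) abort("empty frame")
  q <- quantile(frame, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    return(matrix(0, nrow(frame), ncol(frame)))
  }
  out <- (frame - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Otsu threshold of an adjusted frame
#'
#' The histogram level that maximizes the between-class variance of a
#' two-class split, on a 256-bin histogram over `[0, 1]`. Kept as a small
#' in-package routine because it runs once per movie frame; it agrees with
#' the reference implementation in EBImage to a histogram bin.
#'
#' @param frame Numeric matrix with values in `[0, 1]`.
#' @param levels Number of histogram bins.
#' @return The threshold (bin midpoint) on the `[0, 1]` scale.
#' @export
otsu_threshold <- function(frame, levels = 256L) {
  h <- tabulate(pmin(floor(frame * levels) + 1L, levels), nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(h)
  mu1 <- cumsum(h * mids)
  w2 <- w1[levels] - w1
  mu_t <- mu1[levels]
  # between-class variance for a split after each bin
  bcv <- (mu_t * w1 - mu1 * w1[levels])^2 / (w1 * w2)
  bcv[!is.finite(bcv)] <- 0
  # the maximum is a plateau for well-separated modes; take its middle and
  # return the upper bin edge so `> threshold` splits the classes cleanly
  ties <- which(bcv >= max(bcv) - 1e-12 * max(bcv))
  ties[ceiling(length(ties) / 2)] / levels
}

#' Binarize an adjusted frame
#'
#' Thresholds an intensity-adjusted frame into vessel (bright, `TRUE`) and
#' background pixels. The default threshold is Otsu's method — the level that
#' maximizes between-class variance of the frame histogram; a fixed threshold
#' can be supplied instead.
#'
#' @param frame Numeric matrix with values in `[0, 1]` (see
#'   [adjust_intensity()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold in `(0, 1)`; required for `method = "fixed"`.
#' @return Logical matrix; `TRUE` marks vessel pixels. An all-equal frame
#'   yields an all-`FALSE` mask (flagged downstream as an empty mask).
#' @export
binarize_frame <- function(frame, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (rng[1] < 0 || rng[2] > 1) abort("frame must be adjusted to [0, 1] first")
  if (rng[1] == rng[2]) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  thr <- if (method == "fixed") {
    if (is.null(threshold)) abort("method = 'fixed' requires a threshold")
    threshold
  } else {
    otsu_threshold(frame)
  }
  frame > thr
}

#' Select and clean the vessel component of a binary mask
#'
#' Fills holes, labels 8-connected components, and keeps the one that tracks
#' the vessel: the component containing (or whose centroid is nearest to) the
#' previous frame's centroid when one is given, otherwise the largest by
#' area.
#'
#' When the adjusted intensity frame is supplied, the result also carries a
#' normalized soft field (`soft`): intensities rescaled so the vessel
#' interior level maps to 1 and the background level to 0 (mean levels over
#' the mask and its complement). Its 0.5 level is the half-intensity
#' edge of the lumen, which [minimum_diameter()] samples in preference to the
#' hard mask — the anti-aliased boundary ramp localizes the edge well below
#' the pixel quantization of a binary mask.
#'
#' @param mask Logical matrix (`TRUE` = vessel candidate pixels).
#' @param prev_centroid Optional `c(row, col)` centroid from the previous
#'   frame (0-based), used as a tracking hint.
#' @param intensity Optional adjusted intensity frame (same size as `mask`)
#'   used to build the soft field.
#' @return An object of class `vessel_mask`: list with `mask` (logical
#'   matrix), `centroid_rc` (0-based area centroid), `area_px`,
#'   `touches_border`, `bound_radius_px`, and `soft` (or `NULL`). When the
#'   input mask is empty, `area_px` is 0 and the centroid is `NA` — an
#'   `empty_mask` condition the caller records as a quality flag rather than
#'   an error.
#' @export
select_vessel_component <- function(mask, prev_centroid = NULL,
                                    intensity = NULL) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (!any(mask)) {
    return(structure(
      list(mask = mask, centroid_rc = c(NA_real_, NA_real_),
           area_px = 0L, touches_border = FALSE),
      class = "vessel_mask"
    ))
  }
  filled <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask))) > 0
  lab <- EBImage::bwlabel(filled)
  n_comp <- max(lab)
  if (n_comp > 1L) {
    keep <- 1L
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    if (!is.null(prev_centroid) && !anyNA(prev_centroid)) {
      at <- round(prev_centroid) + 1  # 0-based -> matrix index
      inside <- at[1] >= 1 && at[1] <= nrow(lab) && at[2] >= 1 && at[2] <= ncol(lab)
      hit <- if (inside) lab[at[1], at[2]] else 0L
      if (hit > 0L) {
        keep <- hit
      } else {
        cen_r <- tapply(idx[, 1] - 1, labs, mean)
        cen_c <- tapply(idx[, 2] - 1, labs, mean)
        d2 <- (cen_r - prev_centroid[1])^2 + (cen_c - prev_centroid[2])^2
        keep <- as.integer(names(which.min(d2)))
      }
    } else {
      keep <- as.integer(names(which.max(table(labs))))
    }
    sel <- lab == keep
  } else {
    sel <- filled
  }
  # centroid, border contact and bounding radius from row/col profiles
  rs <- rowSums(sel)
  cs <- colSums(sel)
  area <- sum(rs)
  r_idx <- seq_along(rs) - 1
  c_idx <- seq_along(cs) - 1
  centroid <- c(sum(r_idx * rs), sum(c_idx * cs)) / area
  touches <- rs[1] > 0 || rs[length(rs)] > 0 || cs[1] > 0 || cs[length(cs)] > 0
  rr <- range(r_idx[rs > 0])
  cr <- range(c_idx[cs > 0])
  # farthest bounding-box corner bounds the farthest mask pixel
  radius <- sqrt(max((rr - centroid[1])^2) + max((cr - centroid[2])^2))
  soft <- NULL
  if (!is.null(intensity)) {
    stopifnot(identical(dim(intensity), dim(mask)))
    s_all <- sum(intensity)
    s_fg <- sum(intensity[sel])
    fg <- s_fg / area
    bg <- (s_all - s_fg) / (length(sel) - area)
    if (fg > bg) {
      soft <- (intensity - bg) / (fg - bg)
      soft[soft < 0] <- 0
      soft[soft > 1] <- 1
    }
  }
  structure(
    list(mask = sel, centroid_rc = centroid, area_px = as.integer(area),
         touches_border = touches, bound_radius_px = radius, soft = soft),
    class = "vessel_mask"
  )
}

#' Minimum diameter of a vessel mask
#'
#' Measures the minimum chord of the mask through its centroid: for each angle
#' on a `[0, 180)` degree sweep, the in-mask run containing the centroid is
#' delimited by sub-pixel sampling (bilinear interpolation of the mask at
#' 0.25 px steps, 0.5-crossing interpolated between samples) and the minimum
#' run length over angles is returned. For an elliptical lumen this is the
#' minor axis. If the centroid falls outside the mask (e.g. a crescent after
#' failed hole filling), the longest in-mask run on each line is used instead
#' and the result is flagged as an outlier candidate.
#'
#' Two refinements keep the measurement sub-pixel on hard binary masks.
#' First, chords are measured on a lightly Gaussian-smoothed copy of the mask
#' (`smooth_sigma_px`): the 0.5 level of a smoothed 0/1 edge sits exactly on
#' the edge whatever its orientation, which removes the staircase error of
#' interpolating raw pixels. Second, because a chord profile is locally flat
#' around its minimum while the staircase residual is not, the per-angle
#' profile is smoothed circularly over `profile_smooth_deg` before the
#' minimum is taken — otherwise the minimum over many angles systematically
#' rides the low side of the residual noise.
#'
#' When the lumen can be assumed elliptical — the case for a vessel
#' cross-section, which is a cut through a cylinder — `method = "ellipse"`
#' estimates the minor axis far below the staircase limit by pooling all
#' angles: central chords of an ellipse satisfy
#' `1/D(theta)^2 = c0 + c1 cos(2 theta) + c2 sin(2 theta)`, a linear model
#' fitted by iteratively reweighted (Tukey biweight) least squares, from
#' which `minor = 1/sqrt(c0 + sqrt(c1^2 + c2^2))`. The known inward shift of
#' a smoothed curved edge (half `sigma^2` times curvature per side, curvature
#' `a/b^2` at the minor-axis ends) is added back. The generic `"chord"` sweep
#' remains the definition for arbitrary mask shapes and is the fallback
#' whenever the fit is degenerate.
#'
#' @param vm A [select_vessel_component()] result with non-empty mask.
#' @param angular_step_deg Angular resolution of the sweep, degrees.
#' @param sample_step_px Sampling step along each chord, pixels (<= 0.25 px
#'   keeps sub-pixel diameter changes resolvable).
#' @param method `"chord"`: minimum of the (smoothed) angular chord profile,
#'   valid for any shape. `"ellipse"`: elliptical-profile regression (see
#'   Details), the production estimator for vessel lumens. `"auto"`
#'   (default): the regression when the profile is ellipse-consistent
#'   (relative RMS residual of the harmonic model below 0.1), the sweep
#'   minimum otherwise.
#' @param smooth_sigma_px Gaussian SD for edge smoothing of the mask; 0
#'   disables.
#' @param profile_smooth_deg Half-width of the circular moving average over
#'   the angular profile before its minimum is taken (`"chord"` only); 0
#'   disables.
#' @return A list: `diameter_px`, `angle_deg` (the minor-axis angle),
#'   `centroid_inside`, `method` (as used; `"chord"` when the ellipse fit
#'   fell back), and `lengths_px` (the raw per-angle profile).
#' @export
minimum_diameter <- function(vm, angular_step_deg = 1, sample_step_px = 0.25,
                             method = c("auto", "chord", "ellipse"),
                             smooth_sigma_px = 0.8, profile_smooth_deg = 4) {
  method <- match.arg(method)
  stopifnot(inherits(vm, "vessel_mask"), angular_step_deg > 0,
            sample_step_px > 0, sample_step_px <= 1)
  if (vm$area_px == 0L) abort("cannot measure an empty mask")
  angles <- seq(0, 180 - 1e-9, by = angular_step_deg) * pi / 180
  field <- if (!is.null(vm$soft)) vm$soft else
    matrix(as.numeric(vm$mask), nrow(vm$mask))
  m <- smooth_mask_cpp(field, smooth_sigma_px)
  max_t <- vm$bound_radius_px + 3 * max(smooth_sigma_px, 1) + 2
  res <- chord_lengths_cpp(m, vm$centroid_rc[1], vm$centroid_rc[2],
                           angles, sample_step_px, max_t)
  L <- res$lengths

  if (method != "chord" && res$center_inside && all(L > 0)) {
    fit <- ellipse_profile_fit(L, angles, smooth_sigma_px)
    if (!is.null(fit) && (method == "ellipse" || fit$rel_rmse < 0.1)) {
      return(list(diameter_px = fit$minor_px, angle_deg = fit$angle_deg,
                  centroid_inside = TRUE, method = "ellipse",
                  lengths_px = L))
    }
  }

  Ls <- L
  w <- floor(profile_smooth_deg / angular_step_deg)
  if (w > 0) {
    n <- length(L)
    kern <- rep(1 / (2 * w + 1), 2 * w + 1)
    # the profile is 180-degree periodic
    Lpad <- c(L[(n - w + 1):n], L, L[1:w])
    Ls <- stats::filter(Lpad, kern, sides = 2)[(w + 1):(w + n)]
  }
  i <- which.min(Ls)
  list(
    diameter_px = Ls[i],
    angle_deg = angles[i] * 180 / pi,
    centroid_inside = res$center_inside,
    method = "chord",
    lengths_px = L
  )
}

# Robust linear fit of 1/L^2 on (1, cos 2theta, sin 2theta); returns NULL on a
# degenerate profile so the caller can fall back to the plain sweep.
ellipse_profile_fit <- function(L, angles, smooth_sigma_px) {
  y <- 1 / L^2
  X <- cbind(1, cos(2 * angles), sin(2 * angles))
  w <- rep(1, length(y))
  cf <- NULL
  for (i in 1:3) {
    xtx <- crossprod(X * w)
    if (abs(det(xtx)) < 1e-12) return(NULL)
    cf <- solve(xtx, crossprod(X * w, y * w))
    r <- as.numeric(y - X %*% cf)
    s <- stats::mad(r)
    if (s <= 0) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  if (cf[1] + amp <= 0 || cf[1] - amp <= 0) return(NULL)
  minor <- 1 / sqrt(cf[1] + amp)
  major <- 1 / sqrt(cf[1] - amp)
  # undo the inward shift of the smoothed edge: sigma^2/2 * curvature per side,
  # with curvature semi_major/semi_minor^2 at the minor-axis ends; the
  # linearization fails when the curvature radius approaches sigma, so the
  # correction is capped at a quarter pixel
  minor <- minor + min(smooth_sigma_px^2 * (major / 2) / (minor / 2)^2, 0.25)
  # 1/D^2 is maximal along the minor axis, so atan2(c2, c1)/2 is the angle
  # at which the minimum chord lies
  theta0 <- atan2(cf[3], cf[2]) / 2
  resid <- as.numeric(y - X %*% cf)
  list(minor_px = minor, major_px = major,
       angle_deg = (theta0 * 180 / pi) %% 180,
       rel_rmse = sqrt(mean(resid^2)) / mean(y))
}

#' Extract the per-frame diameter trace of a trial
#'
#' Runs the full per-frame measurement chain — percentile intensity
#' adjustment, binarization, vessel-component selection (with the previous
#' frame's centroid as tracking hint), minimum chord through the centroid —
#' and converts to micrometres. Frames with an empty mask, a border-touching
#' mask, or a centroid outside the mask are flagged and their values replaced
#' by linear interpolation in time between neighboring ok frames; flagged
#' frames are excluded from basal statistics downstream.
#'
#' @param stack An [image_stack()].
#' @param low_pct,high_pct Percentiles for [adjust_intensity()].
#' @param method,threshold Passed to [binarize_frame()].
#' @param angular_step_deg,sample_step_px Passed to [minimum_diameter()].
#' @param estimator Diameter estimator, `"ellipse"` (default; sub-pixel,
#'   assumes an elliptical lumen) or `"chord"` (shape-agnostic sweep
#'   minimum); see [minimum_diameter()].
#' @param max_flagged_frac Maximum tolerated fraction of flagged frames;
#'   above it the trial is rejected as unusable.
#' @return A tibble of class `diameter_trace` with columns `frame` (1-based),
#'   `time_s`, `diameter_um`, `quality` (`"ok"`, `"empty_mask"`,
#'   `"border_contact"`, `"outlier"`), and attributes `frame_rate_hz` and
#'   `pixel_size_um`.
#' @export
extract_diameter_trace <- function(stack,
                                   low_pct = 1, high_pct = 99,
                                   method = c("otsu", "fixed"),
                                   threshold = NULL,
                                   angular_step_deg = 1,
                                   sample_step_px = 0.25,
                                   estimator = c("ellipse", "chord"),
                                   max_flagged_frac = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  nT <- dim(stack$frames)[3]
  vals <- rep(NA_real_, nT)
  qual <- rep("ok", nT)
  prev_centroid <- NULL
  for (k in seq_len(nT)) {
    adj <- adjust_intensity(stack$frames[, , k], low_pct, high_pct)
    bw <- binarize_frame(adj, method, threshold)
    vm <- select_vessel_component(bw, prev_centroid, intensity = adj)
    if (vm$area_px == 0L) {
      qual[k] <- "empty_mask"
      next
    }
    prev_centroid <- vm$centroid_rc
    md <- minimum_diameter(vm, angular_step_deg, sample_step_px,
                           method = estimator)
    vals[k] <- md$diameter_px * stack$pixel_size_um
    if (vm$touches_border) {
      qual[k] <- "border_contact"
    } else if (!md$centroid_inside) {
      qual[k] <- "outlier"
    }
  }
  flagged <- qual != "ok"
  if (mean(flagged) > max_flagged_frac) {
    abort(sprintf("trial quality error: %.0f%% of frames flagged (limit %.0f%%)",
                  100 * mean(flagged), 100 * max_flagged_frac))
  }
  t_s <- (seq_len(nT) - 1) / stack$frame_rate_hz
  if (any(flagged) && any(!flagged)) {
    # flagged frames carry time-interpolated values but keep their flag
    interp <- approx(t_s[!flagged], vals[!flagged], xout = t_s[flagged],
                     rule = 2)$y
    vals[flagged] <- interp
  }
  out <- tibble(frame = seq_len(nT), time_s = t_s,
                diameter_um = vals, quality = qual)
  attr(out, "frame_rate_hz") <- stack$frame_rate_hz
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  class(out) <- c("diameter_trace", class(out))
  out
}
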