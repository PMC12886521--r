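#' Baseline-normalized response map of one reflectance trial
#'
#' Per-pixel fractional reflectance change (dR/R): the mean over the response
#' window minus the mean over the pre-stimulus baseline window, divided by the
#' baseline mean. Under red illumination an activated region absorbs more
#' light, so responses are negative-going.
#'
#' @param stack `H x W x T` numeric array (or an [image_stack()]).
#' @param baseline_frames,response_frames Integer frame indices (1-based) of
#'   the two windows; must be disjoint and within the trial.
#' @return `H x W` numeric matrix of dR/R values.
#' @export
ios_trial_map <- function(stack, baseline_frames, response_frames) {
  a <- if (inherits(stack, "image_stack")) stack$frames else stack
  stopifnot(length(dim(a)) == 3)
  nT <- dim(a)[3]
  if (any(baseline_frames < 1) || any(response_frames > nT) ||
      length(intersect(baseline_frames, response_frames)) > 0) {
    abort("baseline and response windows must be disjoint and within the trial")
  }
  base <- apply(a[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  resp <- apply(a[, , response_frames, drop = FALSE], c(1, 2), mean)
  n_zero <- sum(base <= 0)
  if (n_zero > 0) {
    abort(sprintf("%d pixels have non-positive baseline mean; cannot normalize",
                  n_zero))
  }
  (resp - base) / base
}

#' Activity map of a repeated-stimulation IOS session
#'
#' Sums the baseline-normalized response maps of all trials, the map used to
#' localize the whisker-responsive cortical region before arteriole imaging.
#' The map is linear in its trials and invariant to a global gain applied to
#' any trial's frames.
#'
#' @param trials List of `H x W x T` arrays (or [image_stack()]s) sharing
#'   dimensions, e.g. `simulate_ios_session()$trials`.
#' @param baseline_frames,response_frames As in [ios_trial_map()].
#' @return An object of class `ios_activity_map`: list with `map` (`H x W`
#'   matrix) and `n_trials`.
#' @export
ios_activity_map <- function(trials, baseline_frames, response_frames) {
  stopifnot(is.list(trials), length(trials) >= 1)
  maps <- lapply(trials, ios_trial_map, baseline_frames, response_frames)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), TRUE))) {
    abort("trials have mismatched frame dimensions")
  }
  structure(
    list(map = Reduce(`+`, maps), n_trials = length(trials)),
    class = "ios_activity_map"
  )
}

#' Locate the peak response region of an activity map
#'
#' Thresholds the map at a fraction of its extremum of the requested sign and
#' returns the largest connected suprathreshold region with its intensity-
#' weighted centroid — the footprint overlaid on the vasculature image to
#' identify the activated cortical area.
#'
#' Region extraction runs on a lightly Gaussian-smoothed copy of the map
#' (`smooth_sigma_px`): a hemodynamic response spans tens of pixels, while
#' per-pixel noise peaks would otherwise compete for the extremum on
#' low-SNR maps. Set it to 0 to threshold the raw map. The map itself is
#' never modified.
#'
#' @param map An `ios_activity_map` or plain `H x W` matrix.
#' @param sign `"negative"` (reflectance decrease; the usual case under
#'   630 nm) or `"positive"`.
#' @param fraction_of_peak Threshold as a fraction of the extremum magnitude
#'   (0.5 keeps the full-width-half-maximum region of a single peak).
#' @param smooth_sigma_px Gaussian SD (pixels) of the pre-threshold
#'   smoothing used for localization only.
#' @return A list: `mask` (logical matrix), `centroid_rc` (0-based,
#'   magnitude-weighted), `peak_rc`, `peak_value`.
#' @export
locate_peak_region <- function(map, sign = c("negative", "positive"),
                               fraction_of_peak = 0.5,
                               smooth_sigma_px = 2) {
  sign <- match.arg(sign)
  m <- if (inherits(map, "ios_activity_map")) map$map else map
  stopifnot(is.matrix(m), fraction_of_peak > 0, fraction_of_peak < 1)
  if (diff(range(m)) == 0) abort("constant map has no peak region")
  if (smooth_sigma_px > 0) m <- smooth_mask_cpp(m, smooth_sigma_px)
  s <- if (sign == "negative") -m else m
  peak <- max(s)
  if (peak <= 0) abort(sprintf("map has no %s-going response", sign))
  supra <- s >= fraction_of_peak * peak
  lab <- EBImage::bwlabel(matrix(as.integer(supra), nrow(supra)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  region <- lab == keep
  idx <- which(region, arr.ind = TRUE)
  w <- s[region]
  centroid <- c(sum((idx[, 1] - 1) * w), sum((idx[, 2] - 1) * w)) / sum(w)
  pk <- which(s == peak, arr.ind = TRUE)[1, ]
  list(
    mask = region,
    centroid_rc = centroid,
    peak_rc = c(pk[1] - 1, pk[2] - 1),
    peak_value = if (sign == "negative") -peak else peak
  )
}
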