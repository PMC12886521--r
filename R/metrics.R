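#' Basal diameter of a trial
#'
#' Mean and SD of the measured diameter over the basal window — frames with
#' `basal_window_start_s <= t < stim_onset_s` (half-open, so the onset frame
#' belongs to the response) — using ok-quality frames only.
#'
#' @param trace A [extract_diameter_trace()] tibble (or any tibble with
#'   `time_s`, `diameter_um`, `quality`).
#' @param protocol A [stim_protocol()].
#' @param min_ok_frames Minimum ok frames required in the window.
#' @return A list with `basal_mean_um`, `basal_sd_um`, `n_frames`.
#' @export
compute_basal <- function(trace, protocol, min_ok_frames = 3) {
  stopifnot(inherits(protocol, "stim_protocol"))
  inw <- trace$time_s >= protocol$basal_window_start_s &
    trace$time_s < protocol$stim_onset_s
  ok <- inw & trace$quality == "ok"
  if (sum(ok) < min_ok_frames) {
    abort(sprintf("only %d ok frames in the basal window (need >= %d)",
                  sum(ok), min_ok_frames))
  }
  v <- trace$diameter_um[ok]
  list(basal_mean_um = mean(v), basal_sd_um = sd(v), n_frames = sum(ok))
}

#' Normalize a diameter trace to its basal diameter
#'
#' Expresses the trace as percent of basal (basal diameter = 100%), the scale
#' on which all response parameters are reported. Each trial is normalized to
#' its own basal before trials are averaged.
#'
#' @param trace A diameter trace tibble (`time_s`, `diameter_um`, `quality`).
#' @param protocol A [stim_protocol()].
#' @param basal Optional precomputed [compute_basal()] result.
#' @return A tibble of class `normalized_trace` with columns `time_s`,
#'   `pct`, `quality`, and attributes `protocol`, `basal_mean_um`,
#'   `basal_sd_um`.
#' @export
normalize_trace <- function(trace, protocol, basal = NULL) {
  basal <- basal %||% compute_basal(trace, protocol)
  if (!is.finite(basal$basal_mean_um) || basal$basal_mean_um <= 0) {
    abort("basal diameter must be positive")
  }
  out <- tibble(
    time_s = trace$time_s,
    pct = 100 * trace$diameter_um / basal$basal_mean_um,
    quality = trace$quality
  )
  attr(out, "protocol") <- protocol
  attr(out, "basal_mean_um") <- basal$basal_mean_um
  attr(out, "basal_sd_um") <- basal$basal_sd_um
  class(out) <- c("normalized_trace", class(out))
  out
}

#' Average normalized traces across stimulation trials
#'
#' Pointwise arithmetic mean of per-trial normalized traces (10 per arteriole
#' in the acquisition protocol this pipeline targets), reducing the
#' trial-to-trial variability of awake imaging. Basal statistics are
#' propagated as the mean over trials. A frame is `ok` in the average when it
#' was ok in every trial.
#'
#' @param traces List of [normalize_trace()] tibbles sharing length and
#'   protocol.
#' @return A `normalized_trace` tibble.
#' @export
average_trials <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1)
  n <- vapply(traces, nrow, 0L)
  if (length(unique(n)) != 1) abort("traces have mismatched lengths")
  p0 <- attr(traces[[1]], "protocol")
  for (tr in traces[-1]) {
    p <- attr(tr, "protocol")
    if (!isTRUE(all.equal(unclass(p0), unclass(p)))) {
      abort("traces were acquired under different protocols")
    }
  }
  pct <- rowMeans(vapply(traces, function(tr) tr$pct, numeric(n[1])))
  all_ok <- Reduce(`&`, lapply(traces, function(tr) tr$quality == "ok"))
  out <- tibble(
    time_s = traces[[1]]$time_s,
    pct = pct,
    quality = ifelse(all_ok, "ok", "interpolated")
  )
  attr(out, "protocol") <- p0
  attr(out, "basal_mean_um") <-
    mean(vapply(traces, attr, 0, "basal_mean_um"))
  attr(out, "basal_sd_um") <-
    mean(vapply(traces, attr, 0, "basal_sd_um"))
  attr(out, "n_trials") <- length(traces)
  class(out) <- c("normalized_trace", class(out))
  out
}

#' NVC response parameters of an averaged trace
#'
#' Extracts the four response parameters from a (trial-averaged) normalized
#' trace, evaluated over the closed stimulation window
#' `[stim_onset_s, stim_onset_s + stim_duration_s]`:
#' \describe{
#'   \item{amplitude_pct}{maximum of the normalized trace in the window
#'     (percent of basal); ties resolve to the earliest frame.}
#'   \item{t_max_s}{time from stimulus onset to the amplitude frame.}
#'   \item{t_amp50_s}{time from onset to the first crossing of 50% of the
#'     dilation, i.e. of `100 + (amplitude_pct - 100)/2`, linearly
#'     interpolated between the bracketing frames.}
#'   \item{auc_pct_s}{trapezoidal integral of `(trace - 100)` over the
#'     window, in percent-seconds, so a null response integrates to 0.}
#' }
#'
#' @param avg A [normalize_trace()] / [average_trials()] tibble.
#' @return A one-row tibble with the four parameters, `basal_diameter_um`
#'   (mean basal propagated from the input) and `no_response` (`TRUE` when
#'   the trace never exceeds 100% in the window; then
#'   `t_amp50_s == t_max_s`).
#' @export
compute_metrics <- function(avg) {
  protocol <- attr(avg, "protocol")
  if (is.null(protocol)) abort("trace carries no protocol attribute")
  onset <- protocol$stim_onset_s
  win <- avg$time_s >= onset & avg$time_s <= onset + protocol$stim_duration_s
  if (!any(win)) abort("response window lies outside the trace")
  tw <- avg$time_s[win]
  vw <- avg$pct[win]

  i_peak <- which.max(vw)  # which.max takes the earliest of tied maxima
  amplitude <- vw[i_peak]
  t_max <- tw[i_peak] - onset
  no_response <- amplitude <= 100

  if (no_response) {
    t_amp50 <- t_max
  } else {
    thr <- 100 + 0.5 * (amplitude - 100)
    i_cross <- which(vw >= thr)[1]
    if (i_cross == 1L) {
      t_amp50 <- tw[1] - onset
    } else {
      v1 <- vw[i_cross - 1]; v2 <- vw[i_cross]
      t1 <- tw[i_cross - 1]; t2 <- tw[i_cross]
      t_amp50 <- t1 + (thr - v1) / (v2 - v1) * (t2 - t1) - onset
    }
  }
  auc <- sum(diff(tw) * (utils::head(vw - 100, -1) + utils::tail(vw - 100, -1)) / 2)
  tibble(
    amplitude_pct = amplitude,
    t_max_s = t_max,
    t_amp50_s = t_amp50,
    auc_pct_s = auc,
    basal_diameter_um = attr(avg, "basal_mean_um") %||% NA_real_,
    no_response = no_response
  )
}

#' Longitudinal percent change of a response parameter
#'
#' Change of a response parameter between two timepoints of the same
#' arteriole, as `100 * (current - reference) / reference`. For the amplitude
#' the dilation component `amplitude_pct - 100` is the quantity compared, so
#' a halved dilation reads as -50% rather than a small change on the
#' 100%-offset scale.
#'
#' @param current,reference One-row [compute_metrics()] tibbles (or rows of a
#'   metric table).
#' @param metric Column name: one of `"amplitude_pct"`, `"t_max_s"`,
#'   `"t_amp50_s"`, `"auc_pct_s"`, `"basal_diameter_um"`.
#' @return A one-row tibble: `metric`, `value_reference`, `value_current`,
#'   `change_pct`.
#' @export
percent_change <- function(current, reference, metric) {
  stopifnot(metric %in% c("amplitude_pct", "t_max_s", "t_amp50_s",
                          "auc_pct_s", "basal_diameter_um"))
  cur <- current[[metric]][1]
  ref <- reference[[metric]][1]
  if (metric == "amplitude_pct") {
    cur <- cur - 100
    ref <- ref - 100
  }
  if (!is.finite(ref) || ref == 0) {
    abort(sprintf("reference %s is zero; percent change undefined", metric))
  }
  tibble(
    metric = metric,
    value_reference = ref,
    value_current = cur,
    change_pct = 100 * (cur - ref) / ref
  )
}

#' Measure one arteriole-timepoint: trials to metrics
#'
#' Convenience wrapper chaining the per-trial steps: extract a diameter trace
#' from each trial stack, normalize each to its own basal, average across
#' trials, and compute the response parameters.
#'
#' @param stacks List of [image_stack()] objects (one per stimulation trial).
#' @param protocol A [stim_protocol()].
#' @param ... Passed to [extract_diameter_trace()].
#' @return A one-row [compute_metrics()] tibble.
#' @export
measure_pa <- function(stacks, protocol = stim_protocol(), ...) {
  traces <- lapply(stacks, function(s) {
    normalize_trace(extract_diameter_trace(s, ...), protocol)
  })
  compute_metrics(average_trials(traces))
}
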