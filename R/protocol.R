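#' Whisker-stimulation trial protocol
#'
#' Describes the timing of a single two-photon acquisition trial: total
#' duration, frame rate, stimulus onset and duration, the start of the basal
#' (pre-stimulus) window, and the number of stimulation trials acquired per
#' arteriole. The defaults are the awake-mouse whisker-stimulation protocol
#' this pipeline was designed around: 25 s trials sampled at 9.45 Hz with a
#' 5 s air-puff train starting at second 10, basal window from second 3 to
#' stimulus onset, and 10 trials per penetrating arteriole.
#'
#' The basal window is half-open, `[basal_window_start_s, stim_onset_s)`; the
#' response window is closed, `[stim_onset_s, stim_onset_s + stim_duration_s]`,
#' so the onset frame belongs to the response.
#'
#' @param trial_duration_s Trial length in seconds.
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param stim_onset_s Stimulus onset, seconds from the start of the trial.
#' @param stim_duration_s Stimulus duration in seconds.
#' @param basal_window_start_s Start of the basal window in seconds.
#' @param n_trials Number of stimulation trials per arteriole.
#'
#' @return An object of class `stim_protocol`: a list with the fields above
#'   plus `n_frames`, the derived frame count.
#' @examples
#' p <- stim_protocol()
#' p$n_frames
#' frame_times(p)[1:5]
#' @export
stim_protocol <- function(trial_duration_s = 25,
                          frame_rate_hz = 9.45,
                          stim_onset_s = 10,
                          stim_duration_s = 5,
                          basal_window_start_s = 3,
                          n_trials = 10) {
  stopifnot(
    trial_duration_s > 0, frame_rate_hz > 0,
    stim_onset_s >= 0, stim_duration_s > 0,
    n_trials >= 1
  )
  if (stim_onset_s + stim_duration_s > trial_duration_s) {
    abort("stimulus window extends beyond the trial")
  }
  if (basal_window_start_s >= stim_onset_s) {
    abort("basal window must start before stimulus onset")
  }
  n_frames <- round(trial_duration_s * frame_rate_hz)
  if (n_frames < 2) abort("protocol yields fewer than 2 frames")
  structure(
    list(
      trial_duration_s = trial_duration_s,
      frame_rate_hz = frame_rate_hz,
      stim_onset_s = stim_onset_s,
      stim_duration_s = stim_duration_s,
      basal_window_start_s = basal_window_start_s,
      n_trials = as.integer(n_trials),
      n_frames = as.integer(n_frames)
    ),
    class = "stim_protocol"
  )
}

#' Frame timestamps of a protocol
#'
#' @param protocol A [stim_protocol()].
#' @return Numeric vector of length `protocol$n_frames`; frame `i` is acquired
#'   at `(i - 1) / frame_rate_hz` seconds.
#' @export
frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  (seq_len(protocol$n_frames) - 1) / protocol$frame_rate_hz
}

#' @exportS3Method base::print
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %g s @ %g Hz (%d frames); stim %g-%g s; basal [%g, %g) s; %d trials\n",
    x$trial_duration_s, x$frame_rate_hz, x$n_frames,
    x$stim_onset_s, x$stim_onset_s + x$stim_duration_s,
    x$basal_window_start_s, x$stim_onset_s, x$n_trials
  ))
  invisible(x)
}

# Frame indices (1-based) whose timestamps fall in the basal window [start, onset).
basal_frames <- function(protocol) {
  t <- frame_times(protocol)
  which(t >= protocol$basal_window_start_s & t < protocol$stim_onset_s)
}

# Frame indices in the closed response window [onset, onset + duration].
response_frames <- function(protocol) {
  t <- frame_times(protocol)
  which(t >= protocol$stim_onset_s &
          t <= protocol$stim_onset_s + protocol$stim_duration_s)
}
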