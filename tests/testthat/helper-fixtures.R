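# Shared fixtures built in code at test time.

# A short 10 Hz protocol whose frame grid hits the window boundaries exactly
# (t = 10.0, 12.5, 15.0 s are frames), convenient for closed-form checks.
protocol_10hz <- function() {
  stim_protocol(trial_duration_s = 20, frame_rate_hz = 10,
                stim_onset_s = 10, stim_duration_s = 5,
                basal_window_start_s = 3, n_trials = 10)
}

# Rasterize an ellipse mask (area-coverage > 0.5) in an n x n frame.
ellipse_mask <- function(n, semi_minor, ellipticity = 1, orientation_deg = 0,
                         center = c((n - 1) / 2, (n - 1) / 2)) {
  cov <- lumenpulse:::ellipse_coverage_cpp(
    n, n, center[1], center[2], semi_minor,
    semi_minor * ellipticity, orientation_deg, 8L
  )
  cov > 0.5
}

# An axis-aligned filled square mask of odd side, centered on a pixel.
square_mask <- function(n, side, center = floor((n - 1) / 2)) {
  m <- matrix(FALSE, n, n)
  h <- (side - 1) / 2
  m[(center - h):(center + h) + 1, (center - h):(center + h) + 1] <- TRUE
  m
}

# Build a diameter_trace tibble directly (bypassing imaging).
make_trace <- function(diameter_um, frame_rate_hz = 9.45, pixel_size_um = 0.5,
                       quality = rep("ok", length(diameter_um))) {
  out <- tibble::tibble(
    frame = seq_along(diameter_um),
    time_s = (seq_along(diameter_um) - 1) / frame_rate_hz,
    diameter_um = diameter_um,
    quality = quality
  )
  attr(out, "frame_rate_hz") <- frame_rate_hz
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("diameter_trace", class(out))
  out
}

# Build a normalized_trace tibble directly.
make_norm_trace <- function(pct, protocol, basal_mean_um = 20) {
  out <- tibble::tibble(
    time_s = (seq_along(pct) - 1) / protocol$frame_rate_hz,
    pct = pct,
    quality = rep("ok", length(pct))
  )
  attr(out, "protocol") <- protocol
  attr(out, "basal_mean_um") <- basal_mean_um
  attr(out, "basal_sd_um") <- 0
  class(out) <- c("normalized_trace", class(out))
  out
}

# A balanced metric table with per-mouse constant values (zero within-mouse
# variance) for the degenerate nested-test contract.
constant_within_mouse_table <- function(mouse_values_a, mouse_values_b,
                                        n_pa = 3) {
  rows <- list()
  add <- function(g, i, v) {
    tibble::tibble(group = g, mouse_id = sprintf("%s_m%d", g, i),
                   pa_id = sprintf("%s_m%d_pa%d", g, i, seq_len(n_pa)),
                   value = v)
  }
  dplyr::bind_rows(
    purrr::imap(mouse_values_a, function(v, i) add("a", i, v)),
    purrr::imap(mouse_values_b, function(v, i) add("b", i, v))
  )
}
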