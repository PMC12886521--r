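p_def <- stim_protocol()

test_that("diameter timecourse realizes the parametric dilation", {
  # zero amplitude: flat at basal
  tr0 <- diameter_timecourse(vessel_truth(20, 0, 2.5), p_def)
  expect_equal(tr0, rep(20, p_def$n_frames))

  tr <- diameter_timecourse(vessel_truth(20, 15, 2.5), p_def)
  t <- frame_times(p_def)
  # peak value at the frame nearest onset + t_max
  k <- which.min(abs(t - 12.5))
  expect_equal(tr[k], 23)
  # flat basal before onset; peak only inside the stimulation window
  expect_equal(max(tr[t < 10]), 20)
  expect_equal(max(tr[t >= 10 & t <= 15]), 23)
  # monotone nondecreasing from onset to peak, for both rise shapes
  expect_true(all(diff(tr[t >= 10 & t <= t[k]]) >= 0))
  trg <- diameter_timecourse(vessel_truth(20, 15, 2.5, rise_shape = "gamma"),
                             p_def)
  expect_true(all(diff(trg[t >= 10 & t <= t[k]]) >= -1e-12))
  expect_equal(max(trg), 23)
  # exponential return toward basal with the configured time constant
  tau <- 2
  after <- t > t[k]
  expect_equal(tr[after], 20 + 3 * exp(-(t[after] - t[k]) / tau))
})

test_that("t_max beyond the trial end is rejected", {
  expect_error(diameter_timecourse(vessel_truth(20, 15, t_max_s = 16), p_def),
               "beyond the end")
})

test_that("noiseless rendering is two-valued up to the anti-aliased boundary", {
  vt <- vessel_truth(20, 0, 2.5)
  trial <- render_trial(diameter_timecourse(vt, p_def), vt, noise_model(),
                        p_def, c(72, 72))
  f <- trial$stack$frames[, , 1]
  interior <- sum(f == 1000)
  background <- sum(f == 100)
  between <- sum(f > 100 & f < 1000)
  expect_gt(interior, 0)
  expect_gt(background, 0)
  # the boundary band is one perimeter's worth of pixels, not more
  circumference <- pi * (20 / 0.5) * sqrt((1 + vt$ellipticity^2) / 2)
  expect_lt(between, 2.5 * circumference)
  expect_equal(interior + background + between, length(f))
})

test_that("rendered pixel count matches the analytic disk area", {
  # minor axis 20 px, circular: above-threshold pixel count ~ pi * 10^2
  vt <- vessel_truth(basal_diameter_um = 10, dilation_amplitude_pct = 0,
                     ellipticity = 1, pixel_size_um = 0.5)
  trial <- render_trial(diameter_timecourse(vt, p_def), vt, noise_model(),
                        p_def, c(72, 72))
  f <- trial$stack$frames[, , 1]
  count <- sum(f > (1000 + 100) / 2)
  expect_lt(abs(count - pi * 100), 8)
})

test_that("rendering is deterministic under a seed", {
  vt <- vessel_truth(20, 15, 2.5)
  nm <- noise_model(gaussian_sd = 100, poisson_scale = 0.5,
                    motion_jitter_sd_px = 1)
  tr <- diameter_timecourse(vt, p_def)
  a <- render_trial(tr, vt, nm, p_def, c(72, 72), seed = 99)
  b <- render_trial(tr, vt, nm, p_def, c(72, 72), seed = 99)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- render_trial(tr, vt, nm, p_def, c(72, 72), seed = 100)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("oversized geometry is rejected with a geometry error", {
  vt <- vessel_truth(30, 30, 2.5, center_rc = c(23.5, 23.5))
  expect_error(
    render_trial(diameter_timecourse(vt, p_def), vt,
                 noise_model(motion_jitter_sd_px = 2), p_def, c(48, 48)),
    "geometry error"
  )
})

test_that("session truths aggregate to design means when variances are zero", {
  d0 <- session_design(
    n_mice_per_group = 3,
    groups = list(a = c(amplitude_pct = 0, t_max_s = 0),
                  b = c(amplitude_pct = 0, t_max_s = 1)),
    sd_mouse_amplitude = 0, sd_pa_amplitude = 0,
    sd_mouse_t_max = 0, sd_pa_t_max = 0, seed = 4
  )
  s <- generate_session(d0, render = FALSE)
  expect_true(all(s$truth$dilation_amplitude_pct == 15))
  tm <- tapply(s$truth$t_max_s, s$truth$group, mean)
  expect_equal(unname(tm["b"] - tm["a"]), 1.0)
  # identical groups share identical truths
  expect_equal(unique(s$truth$t_max_s[s$truth$group == "a"]), 2.5)
})

test_that("session truth tables are reproducible and respect structure", {
  d <- session_design(n_mice_per_group = 4, seed = 11)
  s1 <- generate_session(d, render = FALSE)
  s2 <- generate_session(d, render = FALSE)
  expect_identical(s1$truth, s2$truth)
  # each PA belongs to exactly one mouse; 2-6 PAs per mouse
  per_pa <- tapply(s1$truth$mouse_id, s1$truth$pa_id,
                   function(x) length(unique(x)))
  expect_true(all(per_pa == 1))
  per_mouse <- tapply(s1$truth$pa_id, s1$truth$mouse_id,
                      function(x) length(unique(x)))
  expect_true(all(per_mouse >= 2 & per_mouse <= 6))
})

test_that("between-mouse variance of truth amplitudes matches the design", {
  # moment check across many mice: Var(mouse mean amplitude) = sd_mouse^2
  # when the PA-level sd is 0
  d <- session_design(n_mice_per_group = 250, groups = list(a = c(
    amplitude_pct = 0, t_max_s = 0)), sd_mouse_amplitude = 3,
    sd_pa_amplitude = 0, seed = 21)
  s <- generate_session(d, render = FALSE)
  mouse_means <- tapply(s$truth$dilation_amplitude_pct, s$truth$mouse_id, mean)
  v <- var(mouse_means)
  mc_se <- 9 * sqrt(2 / (length(mouse_means) - 1))
  expect_lt(abs(v - 9), 3 * mc_se)
})

test_that("insulin dose follows the printed formula with the range flag", {
  d <- insulin_dose(c(0, 0.025, 0.030), c(300, 400, 600))
  expect_equal(d$dose_ui, c(0, 0.075, 0.135))
  expect_equal(d$dose_per_kg_ui, c(NA, 3.0, 4.5))
  expect_equal(d$in_range, c(FALSE, TRUE, FALSE))
  expect_error(insulin_dose(-1, 100), "non-negative")
})
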