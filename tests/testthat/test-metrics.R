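p10 <- protocol_10hz()

test_that("basal statistics use only the half-open pre-stimulus window", {
  # constant trace
  tr <- make_trace(rep(20, 200), frame_rate_hz = 10)
  b <- compute_basal(tr, p10)
  expect_equal(b$basal_mean_um, 20)
  expect_equal(b$basal_sd_um, 0)

  # values outside [3, 10) s must not contaminate the basal mean
  t <- (seq_len(200) - 1) / 10
  v <- ifelse(t >= 3 & t < 10, 20, 30)
  expect_equal(compute_basal(make_trace(v, 10), p10)$basal_mean_um, 20)

  # alternating 19/21: mean 20, SD by the definitional sample formula
  v2 <- rep(20, 200)
  inw <- t >= 3 & t < 10
  v2[inw] <- rep(c(19, 21), length.out = sum(inw))
  b2 <- compute_basal(make_trace(v2, 10), p10)
  w <- v2[inw]
  expect_equal(b2$basal_mean_um, 20)
  expect_equal(b2$basal_sd_um, sqrt(sum((w - mean(w))^2) / (length(w) - 1)))

  # flagged frames are excluded; too few ok frames rejects
  q <- rep("ok", 200); q[inw] <- "border_contact"
  expect_error(compute_basal(make_trace(v2, 10, quality = q), p10),
               "ok frames")
})

test_that("normalization sets basal diameter to 100%", {
  tr <- make_trace(rep(20, 200), 10)
  nt <- normalize_trace(tr, p10)
  expect_equal(nt$pct, rep(100, 200))
  expect_equal(attr(nt, "basal_mean_um"), 20)

  tr2 <- make_trace(c(rep(20, 150), rep(23, 50)), 10)
  nt2 <- normalize_trace(tr2, p10)
  expect_equal(nt2$pct[200], 115)

  # doubling all diameters leaves the normalized trace unchanged
  tr3 <- make_trace(2 * tr2$diameter_um, 10)
  expect_equal(normalize_trace(tr3, p10)$pct, nt2$pct)

  bad <- list(basal_mean_um = 0, basal_sd_um = 0, n_frames = 10)
  expect_error(normalize_trace(tr, p10, basal = bad), "positive")
})

test_that("trial averaging is the pointwise mean with propagated basal", {
  a <- make_norm_trace(rep(100, 200), p10, basal_mean_um = 18)
  expect_equal(average_trials(list(a))$pct, a$pct)

  x <- sin(seq_len(200) / 9)
  up <- make_norm_trace(100 + x, p10)
  dn <- make_norm_trace(100 - x, p10)
  expect_equal(average_trials(list(up, dn))$pct, rep(100, 200))

  b <- make_norm_trace(rep(100, 200), p10, basal_mean_um = 22)
  expect_equal(attr(average_trials(list(a, b)), "basal_mean_um"), 20)

  other <- make_norm_trace(rep(100, 236), stim_protocol())
  expect_error(average_trials(list(a, other)), "lengths|protocol")
})

test_that("averaging n trials shrinks peak variability like 1/sqrt(n)", {
  set.seed(42)
  truth <- 100 + 15 * exp(-(seq_len(200) / 10 - 12.5)^2 / 2)
  peak_of_avg <- function(n) {
    traces <- lapply(seq_len(n), function(i) {
      make_norm_trace(truth + rnorm(200, 0, 2), p10)
    })
    compute_metrics(average_trials(traces))$amplitude_pct
  }
  sds <- vapply(c(1, 4, 16), function(n) {
    sd(vapply(seq_len(100), function(i) peak_of_avg(n), 0))
  }, 0)
  expect_true(all(diff(sds) < 0))
  slope <- coef(lm(log(sds) ~ log(c(1, 4, 16))))[2]
  expect_gt(slope, -0.65)
  expect_lt(slope, -0.35)
})

test_that("metrics of a triangular pulse match its closed-form geometry", {
  t <- (seq_len(200) - 1) / 10
  v <- rep(100, 200)
  rise <- t >= 10 & t <= 12.5
  fall <- t > 12.5 & t <= 15
  v[rise] <- 100 + 20 * (t[rise] - 10) / 2.5
  v[fall] <- 120 - 20 * (t[fall] - 12.5) / 2.5
  m <- compute_metrics(make_norm_trace(v, p10))
  expect_equal(m$amplitude_pct, 120)
  expect_equal(m$t_max_s, 2.5)
  expect_equal(m$t_amp50_s, 1.25)
  expect_equal(m$auc_pct_s, 50, tolerance = 0.005 * 50)
  expect_false(m$no_response)
})

test_that("null and tied responses resolve deterministically", {
  flat <- compute_metrics(make_norm_trace(rep(100, 200), p10))
  expect_true(flat$no_response)
  expect_equal(flat$amplitude_pct, 100)
  expect_equal(flat$auc_pct_s, 0)
  expect_equal(flat$t_amp50_s, flat$t_max_s)

  # two equal maxima: earliest wins
  t <- (seq_len(200) - 1) / 10
  v <- rep(100, 200)
  v[t == 11] <- 110
  v[t == 13] <- 110
  m <- compute_metrics(make_norm_trace(v, p10))
  expect_equal(m$t_max_s, 1)
})

test_that("t_amp50 never exceeds t_max and AUC is bounded", {
  set.seed(9)
  t <- (seq_len(200) - 1) / 10
  win <- t >= 10 & t <= 15
  for (i in 1:25) {
    v <- 100 + cumsum(rnorm(200, 0, 1.5))
    m <- compute_metrics(make_norm_trace(v, p10))
    expect_lte(m$t_amp50_s, m$t_max_s + 1e-12)
    # the integral of (trace - 100) over the 5 s window is pinched between
    # the window extremes relative to baseline
    expect_lte(m$auc_pct_s, 5 * (m$amplitude_pct - 100) + 1e-9)
    expect_gte(m$auc_pct_s, 5 * (min(v[win]) - 100) - 1e-9)
  }
})

test_that("percent change compares dilation components across timepoints", {
  ref <- tibble::tibble(amplitude_pct = 120, t_max_s = 2, t_amp50_s = 1,
                        auc_pct_s = 40, basal_diameter_um = 20)
  cur <- ref
  expect_equal(percent_change(cur, ref, "t_max_s")$change_pct, 0)
  cur$t_max_s <- 3
  expect_equal(percent_change(cur, ref, "t_max_s")$change_pct, 50)
  # amplitude compares dilation above baseline: 20 -> 10 is -50%
  cur2 <- ref; cur2$amplitude_pct <- 110
  expect_equal(percent_change(cur2, ref, "amplitude_pct")$change_pct, -50)
  ref0 <- ref; ref0$auc_pct_s <- 0
  expect_error(percent_change(cur, ref0, "auc_pct_s"), "zero")
})

test_that("metrics are invariant to uniform rescaling of raw diameters", {
  d <- c(rep(20, 120), 20 + 3 * exp(-((121:200) - 135)^2 / 100))
  m1 <- compute_metrics(normalize_trace(make_trace(d, 10), p10))
  m2 <- compute_metrics(normalize_trace(make_trace(d * 3.2, 10), p10))
  expect_equal(m1$amplitude_pct, m2$amplitude_pct)
  expect_equal(m1$t_max_s, m2$t_max_s)
  expect_equal(m1$auc_pct_s, m2$auc_pct_s)
})
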