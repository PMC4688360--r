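# Build a region_trace directly from a per-frame series.
mk_trace <- function(per_frame, rate = 10, onset = 3) {
  oisr:::new_region_trace(per_frame, rate, onset, "test")
}

test_that("3-frame binning averages consecutive triplets", {
  expect_equal(bin_by_three(c(1, 2, 3, 4, 5, 6)), c(2, 5))
  expect_equal(length(bin_by_three(rep(0, 200))), 67L)  # 66 full + 1 of 2
  expect_equal(bin_by_three(rep(4.2, 30)), rep(4.2, 10))
  expect_equal(bin_by_three(c(1, 2)), 1.5)              # partial-only series
  expect_equal(bin_by_three(c(1, 2, 3, 10)), c(2, 10))  # trailing partial
})

test_that("intensity traces are binned masked means", {
  fr <- array(100, c(6, 6, 30))
  fr[2, 2, ] <- 98   # constant -2% reflectance -> +2% CBV everywhere
  resp <- normalize_to_baseline(movie_from_array(array(100, c(6, 6, 30)),
                                                 onset = 1))
  resp$pct_change[] <- 2
  tr <- intensity_trace(resp, matrix(TRUE, 6, 6), "all")
  expect_equal(tr$values, rep(2, 10), tolerance = 1e-12)
  expect_equal(tr$bin_duration_s, 0.3)

  # single-pixel region reproduces that pixel's binned trace
  one <- matrix(FALSE, 6, 6); one[3, 4] <- TRUE
  resp$pct_change[3, 4, ] <- seq_len(30)
  tr1 <- intensity_trace(resp, one, "pixel")
  expect_equal(tr1$values, bin_by_three(as.numeric(1:30)))

  # random data: equals the brute-force masked mean
  set.seed(8)
  resp$pct_change[] <- rnorm(length(resp$pct_change))
  reg <- matrix(runif(36) < 0.5, 6, 6)
  trr <- intensity_trace(resp, reg, "rand")
  brute <- bin_by_three(vapply(1:30, function(k) {
    mean(resp$pct_change[, , k][reg])
  }, numeric(1)))
  expect_equal(trr$values, brute, tolerance = 1e-12)

  expect_error(intensity_trace(resp, matrix(FALSE, 6, 6)), "empty")
})

test_that("onset detection follows the mean + 2 SD baseline rule", {
  # flat trace: no onset
  expect_true(is.na(onset_time(mk_trace(rep(0, 60)))))

  # zero-noise baseline with a clean step: onset at the first
  # post-stimulus bin that exceeds the epsilon-floored criterion
  step <- c(rep(0, 30), rep(1, 30))
  tr <- mk_trace(step)
  on <- onset_time(tr)
  cand <- which(tr$bin_centers_s >= 3)
  expect_equal(on, tr$bin_centers_s[cand[tr$values[cand] > 2e-6][1L]] - 3)

  # noisy baseline: matches a brute-force scan of the rule
  set.seed(5)
  for (i in 1:20) {
    vals <- rnorm(60, 0, 0.5)
    vals[35:60] <- vals[35:60] + seq(0.3, 3, length.out = 26)
    tr2 <- mk_trace(vals)
    got <- onset_time(tr2)
    thr <- tr2$baseline_mean + 2 * max(tr2$baseline_sd, 1e-6)
    scan <- NA_real_
    for (b in seq_along(tr2$values)) {
      if (tr2$bin_centers_s[b] >= 3 && tr2$values[b] > thr) {
        scan <- tr2$bin_centers_s[b] - 3
        break
      }
    }
    expect_identical(got, scan)
  }
})

test_that("rising slope is the onset-to-peak incline ratio", {
  # linear ramp 0 -> 6% over 3 s from onset: slope 2 %/s between any
  # onset/peak pair on the ramp
  times <- (0:59) / 10
  ramp <- pmax(0, pmin((times - 3) * 2, 6))
  tr <- mk_trace(ramp)
  on <- onset_time(tr)
  pk <- oisr:::trace_peak(tr)
  expect_equal(rising_slope(tr, on, pk), 2, tolerance = 0.05)

  # doubling the peak with fixed timing doubles the slope
  tr2 <- mk_trace(2 * ramp)
  expect_equal(rising_slope(tr2, onset_time(tr2), oisr:::trace_peak(tr2)),
               2 * rising_slope(tr, on, pk), tolerance = 1e-9)

  expect_error(rising_slope(tr, on, list(value = 1, time_s = on)), "after")
  expect_error(rising_slope(tr, NA_real_), "onset")
})

test_that("normalization to 100 rescales without moving the peak", {
  set.seed(9)
  vals <- pmax(0.1, rnorm(60, 1, 0.2))
  vals[40] <- 4
  tr <- mk_trace(vals)
  nm <- normalize_trace_to_100(tr)
  expect_equal(max(nm$values), 100)
  expect_equal(nm$values, tr$values * 100 / max(tr$values))
  expect_equal(which.max(nm$values), which.max(tr$values))
  # idempotence on an already-normalized trace
  again <- normalize_trace_to_100(nm)
  expect_equal(again$values, nm$values, tolerance = 1e-12)
  # time-to-peak is invariant
  expect_equal(oisr:::trace_peak(nm)$time_s, oisr:::trace_peak(tr)$time_s)

  expect_error(normalize_trace_to_100(mk_trace(rep(-1, 60))), "positive")
})

test_that("peak_metrics bundles internally consistent values", {
  p <- tiny_params(n_frames = 200L, stim_onset_s = 5, stim_duration_s = 5,
                   peak_amplitude_pct = 4, dilation_pct = 0, n_trials = 1L)
  sim <- simulate_animal(p)
  filt <- lowpass_filter(average_trials(sim$trials))
  resp <- normalize_to_baseline(filt)
  tr <- intensity_trace(resp, sim$truth$amplitude_map > 3.9, "core")
  m <- peak_metrics(tr)
  expect_s3_class(m, "dynamics_metrics")
  expect_false(is.na(m$onset_time_s))
  expect_lte(m$onset_time_s, m$time_to_peak_s)
  expect_gt(m$max_change_pct, 3.5)
  # slope equals delta / delta-t recomputed from the trace
  onset_bin <- which(abs(tr$bin_centers_s - (5 + m$onset_time_s)) < 1e-9)
  expect_equal(m$rising_slope_pct_per_s,
               (m$max_change_pct - tr$values[onset_bin]) /
                 (m$time_to_peak_s - m$onset_time_s), tolerance = 1e-12)
  # deterministic on identical input
  expect_identical(m, peak_metrics(tr))

  flat <- peak_metrics(mk_trace(rep(0, 60)))
  expect_equal(flat$max_change_pct, 0)
  expect_true(is.na(flat$onset_time_s))
  expect_true(is.na(flat$rising_slope_pct_per_s))
})

test_that("dilation traces recover injected artery widening", {
  # null case: no dilation -> flat trace
  p0 <- tiny_params(image_height_px = 64L, image_width_px = 64L,
                    peak_amplitude_pct = 0, dilation_pct = 0, n_trials = 1L)
  sim0 <- simulate_animal(p0)
  filt0 <- lowpass_filter(average_trials(sim0$trials))
  artery0 <- rasterize_vessels(sim0$truth) & (sim0$truth$dyn_field$key <= 0)
  tr0 <- dilation_trace(filt0, artery0)
  expect_lt(max(abs(tr0$values)), 1e-6)

  # noiseless widening: peak pixel-count change within 25% of the
  # rasterization oracle, strictly increasing across the sweep
  peaks <- c()
  for (d in c(5, 10, 20)) {
    p <- tiny_params(image_height_px = 64L, image_width_px = 64L,
                     peak_amplitude_pct = 0, dilation_pct = d,
                     n_trials = 1L, rng_seed = 17L)
    sim <- simulate_animal(p)
    filt <- lowpass_filter(average_trials(sim$trials))
    artery <- rasterize_vessels(sim$truth) & (sim$truth$dyn_field$key <= 0)
    tr <- dilation_trace(filt, artery)
    pk <- oisr:::trace_peak(tr)
    hood <- oisr:::binary_dilate(artery, 3L)
    rest <- sum(rasterize_vessels(sim$truth, 1) & hood)
    peak_mask <- sum(rasterize_vessels(sim$truth, 1 + d / 100) & hood)
    oracle <- 100 * (peak_mask / rest - 1)
    expect_lt(abs(pk$value - oracle) / oracle, 0.25)
    peaks <- c(peaks, pk$value)
  }
  expect_true(all(diff(peaks) > 0))
})
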