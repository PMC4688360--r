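test_that("trial averaging is the frame-wise mean", {
  m1 <- flat_movie(100)
  m2 <- flat_movie(102)
  avg <- average_trials(trial_set(list(m1, m2)))
  expect_equal(avg$frames, flat_movie(101)$frames)
  # averaging identical movies is the identity
  same <- average_trials(trial_set(list(m1, m1, m1)))
  expect_equal(same$frames, m1$frames)
})

test_that("averaging reduces white-noise SD like 1/sqrt(n)", {
  set.seed(42)
  nt <- 8L
  trials <- lapply(seq_len(nt), function(i) {
    movie_from_array(array(100 + rnorm(100 * 100 * 2), c(100, 100, 2)),
                     onset = 0.1)
  })
  avg <- average_trials(trial_set(trials))
  emp <- sd(avg$frames)
  expect_lt(abs(emp - 1 / sqrt(nt)) / (1 / sqrt(nt)), 0.10)
})

test_that("low-pass filter has unit DC gain and the designed band edges", {
  mv <- flat_movie(100, nt = 100L)
  out <- lowpass_filter(mv, cutoff_hz = 1)
  expect_equal(out$frames, mv$frames, tolerance = 1e-8)

  # oracle: the squared Butterworth magnitude response (two passes)
  ba <- signal::butter(4, 1 / 5, type = "low")
  g_stop <- filtfilt_gain(ba, f = 4, fs = 10)
  g_pass <- filtfilt_gain(ba, f = 0.2, fs = 10)
  t <- (0:199) / 10
  mk <- function(f) {
    movie_from_array(array(rep(100 + sin(2 * pi * f * t), each = 4),
                           c(2, 2, 200)))
  }
  amp_of <- function(mv) (max(mv$frames) - min(mv$frames)) / 2
  hi <- lowpass_filter(mk(4), cutoff_hz = 1)
  lo <- lowpass_filter(mk(0.2), cutoff_hz = 1)
  expect_lt(amp_of(hi), 0.10)            # <= 10% of input amplitude
  # away from the record ends the rejection approaches the analytic gain
  mid <- abs(hi$frames[, , 30:170] - 100)
  expect_lt(max(mid), max(20 * g_stop, 1e-3))
  expect_gt(amp_of(lo), 0.95)            # passband preserved within 5%
  expect_equal(amp_of(lo), g_pass, tolerance = 0.05)

  expect_error(lowpass_filter(mv, cutoff_hz = 5), "cutoff")
  expect_error(lowpass_filter(mv, cutoff_hz = 0), "cutoff")
})

test_that("baseline normalization applies the percent-change formula", {
  fr <- array(100, c(4, 4, 20))
  fr[, , 11:20] <- 96
  mv <- movie_from_array(fr, onset = 1)
  resp <- normalize_to_baseline(mv)
  expect_equal(resp$pct_change[, , 1:10], array(0, c(4, 4, 10)))
  expect_equal(resp$pct_change[1, 1, 15], 4.0)   # reflectance flip
  raw <- normalize_to_baseline(mv, sign = "raw")
  expect_equal(raw$pct_change[1, 1, 15], -4.0)

  flat <- normalize_to_baseline(flat_movie(100))
  expect_true(all(flat$pct_change == 0))

  bad <- fr; bad[2, 3, 1:10] <- 0
  expect_error(normalize_to_baseline(movie_from_array(bad)),
               "row 2, col 3")
})

test_that("crop window arithmetic rounds to odd and checks bounds", {
  fr <- array(runif(100 * 100 * 5) + 1, c(100, 100, 5))
  mv <- movie_from_array(fr, pixel = 0.05, onset = 0.2)
  resp <- normalize_to_baseline(mv)
  crop <- crop_to_window(resp, 50, 50, side_mm = 3)
  expect_equal(dim(crop$pct_change)[1:2], c(61L, 61L))  # 60 px -> odd 61
  # idempotence: cropping the crop with the same center/side is identity
  again <- crop_to_window(crop, 31, 31, side_mm = 3)
  expect_equal(again$pct_change, crop$pct_change)
  expect_error(crop_to_window(resp, 1, 1, side_mm = 3), "outside")
})

test_that("ROI selection finds hot blocks and honors the tie rule", {
  z <- array(0, c(20, 20, 10))
  z[5:11, 8:14, 6:10] <- 5
  resp <- normalize_to_baseline(movie_from_array(100 * (1 - z / 100),
                                                 onset = 0.5))
  roi <- select_roi(resp, 7L)
  expect_equal(c(roi$top_row, roi$left_col), c(5L, 8L))

  # two equal disjoint blocks: lexicographically smaller top-left wins
  z2 <- array(0, c(20, 20, 10))
  z2[12:18, 2:8, 6:10] <- 5
  z2[2:8, 12:18, 6:10] <- 5
  resp2 <- normalize_to_baseline(movie_from_array(100 * (1 - z2 / 100),
                                                  onset = 0.5))
  roi2 <- select_roi(resp2, 7L)
  expect_equal(c(roi2$top_row, roi2$left_col), c(2L, 12L))
})

test_that("ROI selection equals exhaustive search on random fields", {
  set.seed(99)
  for (i in 1:50) {
    fr <- array(100 * (1 - runif(15 * 15 * 8, -0.03, 0.03)), c(15, 15, 8))
    resp <- normalize_to_baseline(movie_from_array(fr, onset = 0.3))
    size <- sample(c(3L, 5L, 7L), 1L)
    got <- select_roi(resp, size)
    want <- roi_bruteforce(resp, size)
    expect_equal(c(got$top_row, got$left_col),
                 c(want$top_row, want$left_col))
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("ROI traces are masked means of the response", {
  fr <- array(100, c(10, 10, 6))
  fr[3, 4, 3:6] <- 96  # one hot pixel inside the ROI, after baseline
  resp <- normalize_to_baseline(movie_from_array(fr, onset = 0.2))
  roi <- structure(list(top_row = 1L, left_col = 1L, size = 7L),
                   class = "roi_selection")
  tr <- roi_trace(resp, roi)
  expect_length(tr, 6L)
  expect_equal(tr, c(0, 0, rep(4 / 49, 4L)), tolerance = 1e-10)

  flat <- normalize_to_baseline(flat_movie(100))
  flat$pct_change[] <- 2
  expect_equal(roi_trace(flat, roi), rep(2, 30L))
})

test_that("peak metrics use the 3-frame moving average from onset", {
  # isolated spike: 3-frame mean (1 + 10 + 1)/3 at the spike center
  tr <- c(rep(0, 10), rep(1, 5), 10, rep(1, 5))
  tr <- c(tr, rep(0, 9))
  m <- max_cbv_and_ttp(tr, frame_rate_hz = 10, stim_onset_s = 0.5)
  expect_equal(m$max_change_pct, 4)
  # frames 15, 16, 17 tie at 4; the earliest wins
  expect_equal(m$peak_frame, 15L)

  flat <- max_cbv_and_ttp(rep(0, 30), 10, 1)
  expect_equal(flat$max_change_pct, 0)
  expect_equal(flat$time_to_peak_s, 0)  # peak at onset for an all-flat trace

  # noiseless synthetic trace peaking 4.6 s after onset
  p <- tiny_params(n_frames = 200L, stim_onset_s = 5, stim_duration_s = 5,
                   peak_amplitude_pct = 4, time_to_peak_s = 4.6,
                   dilation_pct = 0, n_trials = 1L)
  cb <- analyze_cbv(simulate_animal(p)$trials, crop = FALSE)
  expect_lt(abs(cb$metrics$time_to_peak_s - 4.6), 0.1 + 1e-9)
})

test_that("activation extent counts strictly supra-threshold pixels", {
  z <- array(0, c(10, 10, 4))
  z[1:5, 1:5, 2] <- 2          # 25 pixels at 2%
  z[1:5, 1:5, 3] <- 1.0        # exactly at threshold -> excluded
  resp <- normalize_to_baseline(movie_from_array(100 * (1 - z / 100),
                                                 onset = 0.2, pixel = 0.05))
  ext <- activation_extent(resp, 1.0)
  expect_equal(ext, c(0, 25 * 0.0025, 0, 0), tolerance = 1e-9)

  zero <- normalize_to_baseline(flat_movie(50))
  expect_true(all(activation_extent(zero) == 0))

  # monotonicity: raising the threshold never increases the area
  set.seed(3)
  fr <- array(100 * (1 - runif(200 * 6, -0.03, 0.03)), c(10, 20, 6))
  rr <- normalize_to_baseline(movie_from_array(fr, onset = 0.2))
  areas <- vapply(c(0.5, 1, 1.5, 2, 2.5),
                  function(th) sum(activation_extent(rr, th)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("average-then-normalize equals normalize-then-average (noiseless)", {
  p <- tiny_params(peak_amplitude_pct = 3, dilation_pct = 0, n_trials = 3L)
  trials <- simulate_animal(p)$trials
  r1 <- normalize_to_baseline(average_trials(trials))
  per <- lapply(trials, normalize_to_baseline)
  acc <- per[[1L]]$pct_change
  for (k in 2:3) acc <- acc + per[[k]]$pct_change
  expect_equal(r1$pct_change, acc / 3, tolerance = 1e-9)
})

test_that("injected amplitudes are recovered through the full pipeline", {
  for (A in c(2, 6)) {
    p <- scenario_params(image_height_px = 96L, image_width_px = 96L,
                         peak_amplitude_pct = A, time_to_peak_s = 4.6,
                         dilation_pct = 0, noise_sd_pct = 0.2,
                         footprint_radius_mm = 0.6, rng_seed = 100L + A)
    cb <- analyze_cbv(simulate_animal(p)$trials)
    tol <- max(0.3, 0.15 * A)
    expect_lt(abs(cb$metrics$max_change_pct - A), tol)
    expect_lte(abs(cb$metrics$time_to_peak_s - 4.6), 0.3)
  }
})
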