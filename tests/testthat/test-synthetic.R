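test_that("vessel tree generation is deterministic and well-sized", {
  p <- scenario_params(image_height_px = 256L, image_width_px = 256L,
                       rng_seed = 42L)
  t1 <- generate_vessel_tree(p)
  t2 <- generate_vessel_tree(p)
  expect_identical(t1$vessel_mask, t2$vessel_mask)
  expect_identical(t1$segments, t2$segments)

  frac <- mean(t1$vessel_mask)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.30)

  expect_true(sum(t1$segments$type == "artery" & t1$segments$depth == 0L)
              >= 2L)
  # children are narrower than their trunks
  expect_lt(max(t1$segments$width_px[t1$segments$depth == 1L]),
            max(t1$segments$width_px[t1$segments$depth == 0L]))
})

test_that("doubling vessel widths strictly grows the rasterized mask", {
  p1 <- scenario_params(image_height_px = 128L, image_width_px = 128L,
                        rng_seed = 3L)
  p2 <- scenario_params(image_height_px = 128L, image_width_px = 128L,
                        rng_seed = 3L, width_scale = 2)
  n1 <- sum(generate_vessel_tree(p1)$vessel_mask)
  n2 <- sum(generate_vessel_tree(p2)$vessel_mask)
  expect_gt(n2, n1)
})

test_that("too-small images are rejected", {
  expect_error(scenario_params(image_height_px = 16L), "32")
})

test_that("ground truth satisfies its structural invariants", {
  p <- tiny_params(rng_seed = 11L)
  tr <- generate_vessel_tree(p)
  expect_true(all(tr$amplitude_map >= 0))
  expect_equal(max(tr$response_kernel), 1)
  times <- (seq_len(p$n_frames) - 1L) / p$frame_rate_hz
  expect_true(all(tr$response_kernel[times <= p$stim_onset_s] == 0))
  expect_true(all(tr$dilation_profile >= 1))
})

test_that("null scenario renders identical frames", {
  p <- tiny_params(peak_amplitude_pct = 0, dilation_pct = 0)
  tr <- generate_vessel_tree(p)
  trials <- render_trials(p, tr)
  f <- trials[[1L]]$frames
  for (k in seq_len(dim(f)[3L])) {
    expect_equal(f[, , k], f[, , 1L], tolerance = 1e-12)
  }
})

test_that("noiseless rendering follows the baseline modulation equation", {
  p <- tiny_params(peak_amplitude_pct = 4, dilation_pct = 0)
  tr <- generate_vessel_tree(p)
  trials <- render_trials(p, tr)
  f <- trials[[1L]]$frames
  # at a pixel of maximal injected amplitude the noiseless trace dips to
  # exactly (1 - A/100) of its baseline
  idx <- which(tr$amplitude_map == max(tr$amplitude_map))[1L]
  rc <- arrayInd(idx, dim(tr$amplitude_map))
  trace <- f[rc[1L], rc[2L], ]
  expect_equal(min(trace) / trace[1L], 0.96, tolerance = 1e-10)
  # and the whole stack obeys baseline * (1 - amp/100 * kernel)
  k <- sample.int(p$n_frames, 5L)
  for (fr in k) {
    expected <- tr$base_image * (1 - tr$amplitude_map / 100 *
                                   tr$response_kernel[fr])
    expect_equal(f[, , fr], expected, tolerance = 1e-12)
  }
})

test_that("rendering is linear in the injected amplitude", {
  p1 <- tiny_params(peak_amplitude_pct = 2, dilation_pct = 0)
  p2 <- tiny_params(peak_amplitude_pct = 4, dilation_pct = 0)
  tr1 <- generate_vessel_tree(p1)
  tr2 <- generate_vessel_tree(p2)
  f1 <- render_trials(p1, tr1)[[1L]]$frames
  f2 <- render_trials(p2, tr2)[[1L]]$frames
  dip1 <- 1 - f1 / rep(tr1$base_image, dim(f1)[3L])
  dip2 <- 1 - f2 / rep(tr2$base_image, dim(f2)[3L])
  expect_equal(dip2, 2 * dip1, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical trial stacks", {
  p <- tiny_params(noise_sd_pct = 0.5,
                   osc_components = list(c(1, 0.2)), rng_seed = 9L)
  tr <- generate_vessel_tree(p)
  s1 <- render_trials(p, tr)
  s2 <- render_trials(p, tr)
  expect_identical(s1[[1L]]$frames, s1[[1L]]$frames)
  expect_identical(lapply(s1, `[[`, "frames"), lapply(s2, `[[`, "frames"))
  # trials differ from one another (independent noise)
  expect_false(identical(s1[[1L]]$frames, s1[[2L]]$frames))
})

test_that("dilating arteries gain pixels at the response peak", {
  p <- tiny_params(peak_amplitude_pct = 0, dilation_pct = 10)
  tr <- generate_vessel_tree(p)
  rest <- rasterize_vessels(tr, 1)
  peak <- rasterize_vessels(tr, 1 + 10 / 100)
  expect_gt(sum(peak), sum(rest))
  # non-dilating structures are untouched: added pixels are only near
  # dilating segments
  added <- peak & !rest
  expect_true(all(tr$dyn_field$dist[added] <=
                    tr$dyn_field$hw[added] * 1.1 + 1e-9))
  # the rendered frame at the kernel peak darkens exactly the added pixels
  trials <- render_trials(p, tr)
  kpeak <- which.max(tr$response_kernel)
  f <- trials[[1L]]$frames
  expect_true(all(f[, , kpeak][added] < f[, , 1L][added]))
  untouched <- tr$dyn_field$dist > tr$dyn_field$hw * 1.1 + 1.5
  expect_equal(f[, , kpeak][untouched], f[, , 1L][untouched],
               tolerance = 1e-12)
})

test_that("cohort sampling is reproducible and respects degenerate SDs", {
  ctrl <- tiny_params()
  strs <- tiny_params(peak_amplitude_pct = 1.82, time_to_peak_s = 5.43,
                      dilation_pct = 3.49)
  co1 <- generate_cohort(ctrl, strs, n_per_group = 10L, rng_seed = 5L)
  co2 <- generate_cohort(ctrl, strs, n_per_group = 10L, rng_seed = 5L)
  expect_equal(nrow(co1$animals), 20L)
  expect_identical(co1$animals, co2$animals)

  ctrl0 <- tiny_params(amplitude_sd_pct = 0, ttp_sd_s = 0,
                       dilation_sd_pct = 0)
  co0 <- generate_cohort(ctrl0, ctrl0, n_per_group = 5L, rng_seed = 1L)
  amps <- co0$animals$peak_amplitude_pct[co0$animals$group == "control"]
  expect_true(all(amps == amps[1L]))
})

test_that("cohort sampler means converge to the configured group means", {
  ctrl <- scenario_params(preset = "control")
  strs <- scenario_params(preset = "stress")
  n_cohorts <- 100L
  n <- 10L
  means <- matrix(NA_real_, n_cohorts, 2L)
  for (i in seq_len(n_cohorts)) {
    co <- generate_cohort(ctrl, strs, n_per_group = n, rng_seed = i)
    means[i, 1L] <- mean(co$animals$peak_amplitude_pct[
      co$animals$group == "control"])
    means[i, 2L] <- mean(co$animals$peak_amplitude_pct[
      co$animals$group == "stress"])
  }
  sem_ctrl <- ctrl$amplitude_sd_pct / sqrt(n_cohorts * n)
  sem_strs <- strs$amplitude_sd_pct / sqrt(n_cohorts * n)
  expect_lt(abs(mean(means[, 1L]) - ctrl$peak_amplitude_pct), 3 * sem_ctrl)
  # stress samples are floored at zero, which shifts the mean up slightly;
  # allow that analytic truncation bias on top of the Monte-Carlo band
  z <- strs$peak_amplitude_pct / strs$amplitude_sd_pct
  trunc_bias <- strs$amplitude_sd_pct * stats::dnorm(z) -
    strs$peak_amplitude_pct * stats::pnorm(-z)
  expect_lt(abs(mean(means[, 2L]) - strs$peak_amplitude_pct - trunc_bias),
            3 * sem_strs)
})
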