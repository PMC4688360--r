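# Shared fixtures and independent brute-force oracles.

# A small fast scenario: 48 x 48 px at 0.06 mm, short protocol.
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(image_height_px = 48L, image_width_px = 48L,
         pixel_size_mm = 0.06, n_frames = 120L,
         frame_rate_hz = 10, stim_onset_s = 3, stim_duration_s = 3,
         n_trials = 2L, footprint_radius_mm = 0.5,
         noise_sd_pct = 0, osc_components = list(), rng_seed = 7L),
    list(...))
  do.call(scenario_params, args)
}

# A still synthetic cortical scene (vessel tree + seeded sensor noise)
# with its ground truth, for segmentation tests.
seg_scene <- function(seed = 1L, noise = 0.005) {
  p <- tiny_params(image_height_px = 96L, image_width_px = 96L,
                   rng_seed = seed)
  truth <- generate_vessel_tree(p)
  img <- truth$base_image
  if (noise > 0) {
    img <- img + withr::with_seed(seed + 7000L, {
      matrix(rnorm(length(img), 0, noise), nrow(img))
    })
  }
  list(truth = truth, img = img)
}

# Constant-intensity movie.
flat_movie <- function(value = 100, nr = 8L, nc = 8L, nt = 30L,
                       rate = 10, onset = 1) {
  ois_movie(array(value, dim = c(nr, nc, nt)), frame_rate_hz = rate,
            pixel_size_mm = 0.05, stim_onset_s = onset,
            stim_duration_s = 1, n_baseline_frames = round(onset * rate))
}

# Movie from an explicit [row, col, frame] array with default metadata.
movie_from_array <- function(frames, rate = 10, onset = 1, pixel = 0.05) {
  ois_movie(frames, frame_rate_hz = rate, pixel_size_mm = pixel,
            stim_onset_s = onset, stim_duration_s = 1,
            n_baseline_frames = round(onset * rate))
}

# Brute-force per-pixel population SD map (divisor N).
sd_map_bruteforce <- function(frames) {
  d <- dim(frames)
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      v <- frames[i, j, ]
      m <- sum(v) / d[3L]
      out[i, j] <- sqrt(sum((v - m)^2) / d[3L])
    }
  }
  out
}

# Exhaustive ROI search: max window mean of the per-pixel temporal max over
# the stimulation-to-end epoch, ties to smallest (row, col).
roi_bruteforce <- function(response, size) {
  d <- dim(response$pct_change)
  times <- (seq_len(d[3L]) - 1L) / response$frame_rate_hz
  epoch <- which(times >= response$stim_onset_s)
  tmax <- apply(response$pct_change[, , epoch, drop = FALSE], c(1, 2), max)
  best <- -Inf; best_rc <- c(NA, NA)
  for (r in seq_len(d[1L] - size + 1L)) {
    for (cc in seq_len(d[2L] - size + 1L)) {
      s <- mean(tmax[r:(r + size - 1L), cc:(cc + size - 1L)])
      if (s > best) { best <- s; best_rc <- c(r, cc) }
    }
  }
  list(top_row = best_rc[1L], left_col = best_rc[2L], score = best)
}

# Exact two-sided Mann-Whitney p-value by enumerating all group-A rank
# assignments (tie-free samples only; feasible for small n).
mw_exact_bruteforce <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2L, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Magnitude response of a zero-phase (two-pass) digital filter at freq f.
filtfilt_gain <- function(ba, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  H <- sum(ba$b * z^(seq_along(ba$b) - 1)) /
    sum(ba$a * z^(seq_along(ba$a) - 1))
  Mod(H)^2
}
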