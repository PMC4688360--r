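#' Scenario parameters for the synthetic OIS generator
#'
#' Defines one simulated acquisition: field-of-view geometry, the standard
#' stimulation protocol (200 frames at 10 Hz, stimulus at 5 s for 5 s,
#' 8 trials), the injected hemodynamic response (peak percent CBV change,
#' time-to-peak), the pial-artery dilation, and the noise model (additive
#' white noise plus sinusoidal physiological oscillations, both expressed
#' as percent of baseline intensity).
#'
#' The `"control"` preset carries the group means of a healthy cohort
#' (peak CBV change 4.02%, time-to-peak 4.65 s, dilation 6.48%); the
#' `"stress"` preset the blunted response of a chronically stressed cohort
#' (1.82%, 5.43 s, 3.49%). The `*_sd` fields are the corresponding
#' between-animal standard deviations used by [generate_cohort()]
#' (converted from reported standard errors via SD = SEM * sqrt(n), with
#' n = 10 for the CBV metrics and n = 6 / 5 for dilation).
#'
#' @param preset `"control"` (default) or `"stress"`: selects the group
#'   defaults above. Any explicit argument overrides the preset.
#' @param image_height_px,image_width_px field of view in pixels (>= 32).
#' @param pixel_size_mm pixel pitch in mm.
#' @param n_frames,frame_rate_hz frames per trial and acquisition rate.
#' @param stim_onset_s,stim_duration_s stimulation envelope (s).
#' @param n_trials number of repeated trials.
#' @param peak_amplitude_pct injected peak CBV change (%, >= 0), rendered
#'   as a reflectance *decrease* at 570 nm.
#' @param time_to_peak_s kernel peak latency from stimulation onset (s).
#' @param dilation_pct peak artery width increase (%, >= 0).
#' @param footprint_radius_mm radius of the uniform core of the responsive
#'   footprint; amplitude tapers to 0 by 1.5x this radius.
#' @param noise_sd_pct white-noise SD, % of baseline intensity.
#' @param osc_components list of `c(frequency_hz, amplitude_pct)` global
#'   sinusoids (defaults: 1 Hz at 0.2% "respiration", 4 Hz at 0.1%
#'   "cardiac alias").
#' @param amplitude_sd_pct,ttp_sd_s,dilation_sd_pct between-animal SDs
#'   used when sampling cohorts.
#' @param n_trunks,trunk_width_px,vein_width_px,n_veins,width_scale vessel
#'   geometry: number of artery trunks, trunk width (px), vein width (px),
#'   number of veins, and a global width multiplier.
#' @param tissue_level,vessel_level,vein_level rendered reflectance levels
#'   (arbitrary units; vessels darker than tissue).
#' @param kernel_shape shape parameter of the gamma-variate response
#'   kernel (larger = narrower peak).
#' @param rng_seed integer seed controlling geometry and noise.
#' @return An object of class `scenario_params` (a validated named list).
#' @export
scenario_params <- function(preset = c("control", "stress"),
                            image_height_px = 128L, image_width_px = 128L,
                            pixel_size_mm = 0.05,
                            n_frames = 200L, frame_rate_hz = 10,
                            stim_onset_s = 5, stim_duration_s = 5,
                            n_trials = 8L,
                            peak_amplitude_pct = NULL,
                            time_to_peak_s = NULL,
                            dilation_pct = NULL,
                            footprint_radius_mm = 0.75,
                            noise_sd_pct = 0.2,
                            osc_components = list(c(1, 0.2), c(4, 0.1)),
                            amplitude_sd_pct = NULL,
                            ttp_sd_s = NULL,
                            dilation_sd_pct = NULL,
                            n_trunks = 2L, trunk_width_px = 6,
                            vein_width_px = 9, n_veins = 1L,
                            width_scale = 1,
                            tissue_level = 1, vessel_level = 0.55,
                            vein_level = 0.55,
                            kernel_shape = 3,
                            rng_seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    control = list(peak_amplitude_pct = 4.02, time_to_peak_s = 4.65,
                   dilation_pct = 6.48,
                   amplitude_sd_pct = 0.34 * sqrt(10),
                   ttp_sd_s = 0.25 * sqrt(10),
                   dilation_sd_pct = 2.38 * sqrt(6)),
    stress  = list(peak_amplitude_pct = 1.82, time_to_peak_s = 5.43,
                   dilation_pct = 3.49,
                   amplitude_sd_pct = 0.32 * sqrt(10),
                   ttp_sd_s = 0.59 * sqrt(10),
                   dilation_sd_pct = 1.02 * sqrt(5)))
  if (is.null(peak_amplitude_pct)) peak_amplitude_pct <- defaults$peak_amplitude_pct
  if (is.null(time_to_peak_s)) time_to_peak_s <- defaults$time_to_peak_s
  if (is.null(dilation_pct)) dilation_pct <- defaults$dilation_pct
  if (is.null(amplitude_sd_pct)) amplitude_sd_pct <- defaults$amplitude_sd_pct
  if (is.null(ttp_sd_s)) ttp_sd_s <- defaults$ttp_sd_s
  if (is.null(dilation_sd_pct)) dilation_sd_pct <- defaults$dilation_sd_pct

  p <- list(group = preset,
            image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            pixel_size_mm = pixel_size_mm,
            n_frames = as.integer(n_frames),
            frame_rate_hz = frame_rate_hz,
            stim_onset_s = stim_onset_s,
            stim_duration_s = stim_duration_s,
            n_trials = as.integer(n_trials),
            peak_amplitude_pct = peak_amplitude_pct,
            time_to_peak_s = time_to_peak_s,
            dilation_pct = dilation_pct,
            footprint_radius_mm = footprint_radius_mm,
            noise_sd_pct = noise_sd_pct,
            osc_components = osc_components,
            amplitude_sd_pct = amplitude_sd_pct,
            ttp_sd_s = ttp_sd_s,
            dilation_sd_pct = dilation_sd_pct,
            n_trunks = as.integer(n_trunks),
            trunk_width_px = trunk_width_px,
            vein_width_px = vein_width_px,
            n_veins = as.integer(n_veins),
            width_scale = width_scale,
            tissue_level = tissue_level,
            vessel_level = vessel_level,
            vein_level = vein_level,
            kernel_shape = kernel_shape,
            rng_seed = as.integer(rng_seed))
  validate_scenario_params(p)
  structure(p, class = "scenario_params")
}

validate_scenario_params <- function(p) {
  if (p$image_height_px < 32L || p$image_width_px < 32L) {
    stop("image too small: both dimensions must be >= 32 px")
  }
  if (p$n_frames / p$frame_rate_hz <= p$stim_onset_s + p$stim_duration_s) {
    stop("recording must outlast stimulation onset + duration")
  }
  stopifnot(p$pixel_size_mm > 0, p$n_trials >= 1L,
            p$peak_amplitude_pct >= 0, p$dilation_pct >= 0,
            p$time_to_peak_s > 0, p$footprint_radius_mm > 0,
            p$noise_sd_pct >= 0, p$width_scale > 0,
            p$vessel_level > 0, p$vessel_level < p$tissue_level,
            p$kernel_shape > 0)
  invisible(p)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario_params> [%s] %d x %d px @ %g mm, %d frames @ %g Hz, ",
    "%d trials\n  amplitude %.2f%%, ttp %.2f s, dilation %.2f%%, ",
    "noise %.2f%%, seed %d\n"),
    x$group, x$image_height_px, x$image_width_px, x$pixel_size_mm,
    x$n_frames, x$frame_rate_hz, x$n_trials, x$peak_amplitude_pct,
    x$time_to_peak_s, x$dilation_pct, x$noise_sd_pct, x$rng_seed))
  invisible(x)
}

# Gamma-variate hemodynamic kernel on the frame-time grid, zero before
# stimulation onset, normalized so its maximum over the grid is exactly 1.
response_kernel_for <- function(params) {
  t <- (seq_len(params$n_frames) - 1L) / params$frame_rate_hz
  u <- (t - params$stim_onset_s) / params$time_to_peak_s
  k <- ifelse(u > 0, u^params$kernel_shape *
                exp(params$kernel_shape * (1 - u)), 0)
  m <- max(k)
  if (m > 0) k <- k / m
  k
}

# Minimum distance from every pixel of an (nr x nc) grid inside a bounding
# box to the segment (r0,c0)-(r1,c1); updates key/dist/hw matrices in place
# (returned as a list) where key = dist - halfwidth improves.
update_segment_field <- function(field, r0, c0, r1, c1, hw, nr, nc,
                                 margin) {
  rlo <- max(1L, floor(min(r0, r1) - hw - margin))
  rhi <- min(nr, ceiling(max(r0, r1) + hw + margin))
  clo <- max(1L, floor(min(c0, c1) - hw - margin))
  chi <- min(nc, ceiling(max(c0, c1) + hw + margin))
  if (rlo > rhi || clo > chi) return(field)
  rr <- rlo:rhi; cc <- clo:chi
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vr <- r1 - r0; vc <- c1 - c0
  len2 <- vr * vr + vc * vc
  tt <- if (len2 == 0) {
    matrix(0, length(rr), length(cc))
  } else {
    pmin(pmax(((R - r0) * vr + (C - c0) * vc) / len2, 0), 1)
  }
  d <- sqrt((R - (r0 + tt * vr))^2 + (C - (c0 + tt * vc))^2)
  key <- d - hw
  sub <- field$key[rr, cc, drop = FALSE]
  better <- key < sub
  if (any(better)) {
    sub[better] <- key[better]
    field$key[rr, cc] <- sub
    dsub <- field$dist[rr, cc, drop = FALSE]
    dsub[better] <- d[better]
    field$dist[rr, cc] <- dsub
    hsub <- field$hw[rr, cc, drop = FALSE]
    hsub[better] <- hw
    field$hw[rr, cc] <- hsub
  }
  field
}

new_field <- function(nr, nc) {
  list(key = matrix(Inf, nr, nc),
       dist = matrix(Inf, nr, nc),
       hw = matrix(0, nr, nc))
}

# Random-walk polyline from a starting point/heading; returns a numeric
# matrix of segment rows (r0, c0, r1, c1, width, type_code, depth) —
# type_code 1 = artery, 2 = vein. Kept numeric for cheap accumulation.
walk_polyline <- function(r, c, heading, n_steps, step_len, width, type,
                          depth, nr, nc, jitter_deg = 12) {
  type_code <- if (type == "artery") 1 else 2
  segs <- matrix(NA_real_, n_steps, 7L)
  used <- 0L
  for (s in seq_len(n_steps)) {
    heading <- heading + stats::runif(1, -jitter_deg, jitter_deg) * pi / 180
    r1 <- r + step_len * sin(heading)
    c1 <- c + step_len * cos(heading)
    used <- used + 1L
    segs[used, ] <- c(r, c, r1, c1, width, type_code, depth)
    r <- r1; c <- c1
    if (r < -step_len || r > nr + step_len ||
        c < -step_len || c > nc + step_len) break
  }
  segs[seq_len(used), , drop = FALSE]
}

border_start <- function(side, nr, nc) {
  u <- stats::runif(1, 0.15, 0.85)
  switch(side,
    top    = list(r = 1, c = u * nc, heading = pi / 2),
    bottom = list(r = nr, c = u * nc, heading = -pi / 2),
    left   = list(r = u * nr, c = 1, heading = 0),
    right  = list(r = u * nr, c = nc, heading = pi))
}

#' Generate a synthetic pial vessel tree with ground truth
#'
#' Draws a branching arterial tree (two or more trunks entering from the
#' image border, children at ~0.65x the parent width) plus wider
#' non-dilating veins, rasterizes it into a resting vessel mask, and builds
#' the full ground truth for one animal: the injected amplitude map (a
#' uniform core of `peak_amplitude_pct` within `footprint_radius_mm`,
#' cosine-tapered to zero by 1.5x the radius), the gamma-variate response
#' kernel, and the per-frame artery width-scale profile. Artery segments
#' whose midpoint falls within the response footprint dilate; veins and
#' distal arteries do not.
#'
#' Deterministic for a fixed `rng_seed`.
#'
#' @param params a [scenario_params] object.
#' @return An object of class `ois_truth` with elements `vessel_mask`
#'   (logical matrix, vessel at rest), `segments` (data.frame of
#'   centerline segments with widths), `amplitude_map` (matrix, %),
#'   `response_kernel` (per-frame weights in `[0, 1]`, max exactly 1),
#'   `dilation_profile` (per-frame width scale), `base_image` (resting
#'   reflectance), and internal distance fields used by the renderer.
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  nr <- params$image_height_px; nc <- params$image_width_px
  L <- min(nr, nc)
  with_seed(params$rng_seed, {
    sides <- sample(c("top", "bottom", "left", "right"))
    pieces <- list()
    # artery trunks with children and grandchildren; the first trunk is
    # aimed at the image center — the field of view of this kind of
    # recording is framed on the responsive region and its feeding artery
    for (i in seq_len(params$n_trunks)) {
      st <- border_start(sides[1L + (i - 1L) %% 4L], nr, nc)
      if (i == 1L) {
        st$heading <- atan2((nr + 1) / 2 - st$r, (nc + 1) / 2 - st$c)
      }
      trunk <- walk_polyline(st$r, st$c, st$heading,
                             n_steps = sample(4:6, 1), step_len = L / 5,
                             width = params$trunk_width_px * params$width_scale,
                             type = "artery", depth = 0L, nr, nc)
      pieces[[length(pieces) + 1L]] <- trunk
      for (v in seq_len(nrow(trunk))) {
        if (stats::runif(1) > 0.6) next
        ang <- atan2(trunk[v, 3L] - trunk[v, 1L], trunk[v, 4L] - trunk[v, 2L])
        ang <- ang + sample(c(-1, 1), 1) * stats::runif(1, 30, 55) * pi / 180
        child <- walk_polyline(trunk[v, 3L], trunk[v, 4L], ang,
                               n_steps = sample(2:4, 1), step_len = L / 8,
                               width = trunk[v, 5L] * 0.65,
                               type = "artery", depth = 1L, nr, nc)
        pieces[[length(pieces) + 1L]] <- child
        if (child[1L, 5L] * 0.65 >= 1.5 && stats::runif(1) < 0.5) {
          ang2 <- ang + sample(c(-1, 1), 1) * stats::runif(1, 30, 55) * pi / 180
          pieces[[length(pieces) + 1L]] <- walk_polyline(
            child[nrow(child), 3L], child[nrow(child), 4L], ang2,
            n_steps = 2, step_len = L / 10,
            width = child[1L, 5L] * 0.65,
            type = "artery", depth = 2L, nr, nc)
        }
      }
    }
    # veins: wider, non-dilating
    for (i in seq_len(params$n_veins)) {
      st <- border_start(sides[1L + (params$n_trunks + i - 1L) %% 4L], nr, nc)
      pieces[[length(pieces) + 1L]] <- walk_polyline(
        st$r, st$c, st$heading, n_steps = sample(4:5, 1), step_len = L / 5,
        width = params$vein_width_px * params$width_scale,
        type = "vein", depth = 0L, nr, nc)
    }
    sm <- do.call(rbind, pieces)
    segs <- data.frame(
      r0 = sm[, 1L], c0 = sm[, 2L], r1 = sm[, 3L], c1 = sm[, 4L],
      width_px = sm[, 5L],
      type = c("artery", "vein")[sm[, 6L]],
      depth = as.integer(sm[, 7L]),
      stringsAsFactors = FALSE)
    segs$halfwidth_px <- segs$width_px / 2

    # response footprint and which artery segments dilate
    center <- c(r = (nr + 1) / 2, c = (nc + 1) / 2)
    fp_px <- params$footprint_radius_mm / params$pixel_size_mm
    mid_r <- (segs$r0 + segs$r1) / 2
    mid_c <- (segs$c0 + segs$c1) / 2
    seg_d <- sqrt((mid_r - center["r"])^2 + (mid_c - center["c"])^2)
    segs$dilates <- segs$type == "artery" & seg_d <= 1.5 * fp_px
    if (!any(segs$dilates)) {
      # guarantee a responsive feeding artery: the branch nearest the
      # footprint dilates even when the random walk strays off-center
      is_art <- segs$type == "artery"
      nearest <- min(seg_d[is_art])
      segs$dilates <- is_art & seg_d <= nearest + L / 10
    }

    # distance fields: static structures vs dilating artery segments
    max_scale <- 1 + params$dilation_pct / 100
    static <- new_field(nr, nc)
    dyn <- new_field(nr, nc)
    for (i in seq_len(nrow(segs))) {
      hw <- segs$halfwidth_px[i]
      if (segs$dilates[i]) {
        dyn <- update_segment_field(dyn, segs$r0[i], segs$c0[i],
                                    segs$r1[i], segs$c1[i], hw, nr, nc,
                                    margin = hw * (max_scale - 1) + 2)
      } else {
        static <- update_segment_field(static, segs$r0[i], segs$c0[i],
                                       segs$r1[i], segs$c1[i], hw, nr, nc,
                                       margin = 2)
      }
    }

    vessel_mask <- (static$key <= 0) | (dyn$key <= 0)
    if (sum(vessel_mask) == 0L) stop("degenerate vessel tree: empty mask")

    # amplitude map: uniform core, cosine taper to 1.5 x footprint radius
    R <- matrix(seq_len(nr), nr, nc)
    C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    rad <- sqrt((R - center["r"])^2 + (C - center["c"])^2)
    a <- ifelse(rad <= fp_px, 1,
                ifelse(rad >= 1.5 * fp_px, 0,
                       0.5 * (1 + cos(pi * (rad - fp_px) / (0.5 * fp_px)))))
    amplitude_map <- params$peak_amplitude_pct * a

    kernel <- response_kernel_for(params)
    dilation_profile <- 1 + params$dilation_pct / 100 * kernel

    base_image <- render_geometry(params, static, dyn, scale = 1)

    structure(
      list(vessel_mask = vessel_mask,
           segments = segs,
           amplitude_map = amplitude_map,
           response_kernel = kernel,
           dilation_profile = dilation_profile,
           base_image = base_image,
           footprint_center_px = center,
           footprint_radius_px = fp_px,
           static_field = static,
           dyn_field = dyn),
      class = "ois_truth")
  })
}

# Anti-aliased coverage of a distance field at a width scale: 1 inside the
# vessel, 0 one pixel outside, linear in between (sub-pixel edge rendering).
field_coverage <- function(field, scale = 1) {
  pmin(pmax(field$hw * scale + 0.5 - field$dist, 0), 1)
}

# Resting reflectance image for given distance fields at a width scale
# applied to the dilating arteries.
render_geometry <- function(params, static, dyn, scale = 1) {
  dark_static <- field_coverage(static, 1) *
    (params$tissue_level - params$vessel_level)
  dark_dyn <- field_coverage(dyn, scale) *
    (params$tissue_level - params$vessel_level)
  params$tissue_level - pmax(dark_static, dark_dyn)
}

#' Rasterize the ground-truth vessels at a given artery width scale
#'
#' The reference rasterization used as the oracle for pixel-count dilation:
#' a pixel is vessel when its distance to the nearest centerline is at most
#' the segment halfwidth (dilating segments scaled by `scale`).
#'
#' @param truth an `ois_truth`.
#' @param scale width multiplier applied to dilating artery segments.
#' @return logical matrix.
#' @export
rasterize_vessels <- function(truth, scale = 1) {
  stopifnot(inherits(truth, "ois_truth"))
  (truth$static_field$dist <= truth$static_field$hw) |
    (truth$dyn_field$dist <= truth$dyn_field$hw * scale)
}

#' Render the repeated stimulation trials of one synthetic animal
#'
#' Builds the noiseless movie — each pixel's trace is
#' `baseline * (1 - amplitude_map/100 * kernel[t])`, with dilating artery
#' segments re-rendered each frame at the width scale
#' `dilation_profile[t]` — then adds, independently per trial, global
#' sinusoidal oscillations with random phases and per-pixel white noise
#' (both scaled by the local baseline intensity). A CBV increase is a
#' reflectance *decrease* (570 nm isosbestic convention); the analysis
#' layer flips the sign back.
#'
#' Trial noise uses sequential draws from an RNG seeded at
#' `rng_seed + 1`, so trials are mutually independent yet the whole set is
#' reproducible.
#'
#' @param params a [scenario_params].
#' @param truth the matching [generate_vessel_tree()] output.
#' @return A [trial_set] of `n_trials` [ois_movie] objects.
#' @export
render_trials <- function(params, truth) {
  stopifnot(inherits(params, "scenario_params"), inherits(truth, "ois_truth"))
  nr <- params$image_height_px; nc <- params$image_width_px
  if (!identical(dim(truth$vessel_mask), c(nr, nc))) {
    stop("ground truth does not match scenario dimensions")
  }
  nt <- params$n_frames
  npix <- nr * nc
  base_vec <- as.vector(truth$base_image)
  dark_coef <- params$tissue_level - params$vessel_level

  # noiseless stack: start from the resting image, overwrite pixels near
  # dilating arteries frame-by-frame, then apply the CBV modulation
  noiseless <- matrix(base_vec, npix, nt)
  scale_t <- truth$dilation_profile
  if (any(scale_t != 1)) {
    dynf <- truth$dyn_field
    reach <- dynf$hw * max(scale_t) + 0.5 - dynf$dist
    sel <- which(as.vector(reach) > 0 | as.vector(dynf$key) <= 0)
    if (length(sel) > 0L) {
      hw <- as.vector(dynf$hw)[sel]
      d <- as.vector(dynf$dist)[sel]
      static_dark <- as.vector(
        field_coverage(truth$static_field, 1) * dark_coef)[sel]
      cov_dyn <- pmin(pmax(outer(hw, scale_t) + 0.5 - d, 0), 1)
      dark <- pmax(cov_dyn * dark_coef, static_dark)
      noiseless[sel, ] <- params$tissue_level - dark
    }
  }
  amp_vec <- as.vector(truth$amplitude_map) / 100
  noiseless <- noiseless * (1 - outer(amp_vec, truth$response_kernel))

  times <- (seq_len(nt) - 1L) / params$frame_rate_hz
  meta <- list(frame_rate_hz = params$frame_rate_hz,
               pixel_size_mm = params$pixel_size_mm,
               stim_onset_s = params$stim_onset_s,
               stim_duration_s = params$stim_duration_s,
               n_baseline_frames =
                 as.integer(round(params$stim_onset_s * params$frame_rate_hz)))
  # Kinderman-Ramage normals: ~1.5x faster than inversion for the large
  # per-frame noise fields, still seed-reproducible
  trials <- with_seed(params$rng_seed + 1L, normal_kind = "Kinderman-Ramage", {
    lapply(seq_len(params$n_trials), function(i) {
      osc <- numeric(nt)
      for (comp in params$osc_components) {
        phase <- stats::runif(1, 0, 2 * pi)
        osc <- osc + comp[2] / 100 * sin(2 * pi * comp[1] * times + phase)
      }
      fr <- .render_noise(noiseless, base_vec, osc,
                          params$noise_sd_pct / 100)
      dim(fr) <- c(nr, nc, nt)
      new_ois_movie(fr, meta)
    })
  })
  structure(trials, class = "trial_set")
}

#' Simulate one synthetic animal end to end
#'
#' Convenience wrapper: [generate_vessel_tree()] + [render_trials()].
#'
#' @param params a [scenario_params].
#' @return list with elements `params`, `truth`, `trials`.
#' @export
simulate_animal <- function(params) {
  truth <- generate_vessel_tree(params)
  list(params = params, truth = truth, trials = render_trials(params, truth))
}

#' Sample a two-group synthetic cohort
#'
#' Draws per-animal injected parameters around each group's means using the
#' between-animal SDs stored in the group's [scenario_params]
#' (`peak_amplitude_pct` and `dilation_pct` from normal distributions
#' floored at 0; `time_to_peak_s` clamped to `[0.5, 10]` s for
#' renderability), and assigns each animal a deterministic sub-seed. Trial
#' stacks are rendered on demand by [render_animal()] — a full cohort of
#' movies would not fit comfortably in memory.
#'
#' @param control,stress [scenario_params] for the two groups.
#' @param n_per_group animals per group (>= 2).
#' @param rng_seed cohort-level seed.
#' @return An object of class `ois_cohort`: list with `animals` (the
#'   ground-truth table of injected parameters: `animal`, `group`,
#'   `peak_amplitude_pct`, `time_to_peak_s`, `dilation_pct`, `seed`) and
#'   the two group parameter sets.
#' @export
generate_cohort <- function(control, stress, n_per_group, rng_seed = 1L) {
  stopifnot(inherits(control, "scenario_params"),
            inherits(stress, "scenario_params"),
            n_per_group >= 2L)
  with_seed(rng_seed, {
    sample_group <- function(p, group, offset) {
      data.frame(
        animal = sprintf("%s_%02d", group, seq_len(n_per_group)),
        group = group,
        peak_amplitude_pct = pmax(0, stats::rnorm(
          n_per_group, p$peak_amplitude_pct, p$amplitude_sd_pct)),
        time_to_peak_s = pmin(pmax(stats::rnorm(
          n_per_group, p$time_to_peak_s, p$ttp_sd_s), 0.5), 10),
        dilation_pct = pmax(0, stats::rnorm(
          n_per_group, p$dilation_pct, p$dilation_sd_pct)),
        seed = as.integer((rng_seed * 1000L + offset + seq_len(n_per_group))
                          %% .Machine$integer.max),
        stringsAsFactors = FALSE)
    }
    animals <- rbind(sample_group(control, "control", 0L),
                     sample_group(stress, "stress", 500L))
    structure(list(animals = animals, control = control, stress = stress),
              class = "ois_cohort")
  })
}

#' @export
print.ois_cohort <- function(x, ...) {
  cat(sprintf("<ois_cohort> %d animals (%s)\n", nrow(x$animals),
              paste(sprintf("%s n=%d", unique(x$animals$group),
                            table(x$animals$group)[unique(x$animals$group)]),
                    collapse = ", ")))
  invisible(x)
}

#' Render the trial set of one cohort animal
#'
#' @param cohort an `ois_cohort`.
#' @param i animal row index in `cohort$animals`.
#' @return list with `params`, `truth`, `trials` for that animal.
#' @export
render_animal <- function(cohort, i) {
  stopifnot(inherits(cohort, "ois_cohort"),
            i >= 1L, i <= nrow(cohort$animals))
  row <- cohort$animals[i, ]
  base <- if (row$group == "control") cohort$control else cohort$stress
  p <- base
  p$peak_amplitude_pct <- row$peak_amplitude_pct
  p$time_to_peak_s <- row$time_to_peak_s
  p$dilation_pct <- row$dilation_pct
  p$rng_seed <- row$seed
  validate_scenario_params(p)
  simulate_animal(p)
}
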