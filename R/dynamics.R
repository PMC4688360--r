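#' Average a per-frame series in non-overlapping 3-frame bins
#'
#' Consecutive groups of three frames are averaged (0.3 s bins at 10 Hz);
#' a final partial bin is averaged over however many frames it holds.
#'
#' @param x per-frame numeric series.
#' @param bin number of frames per bin (default 3).
#' @return per-bin numeric series of length `ceiling(length(x) / bin)`.
#' @export
bin_by_three <- function(x, bin = 3L) {
  n <- length(x)
  stopifnot(n >= 1L, bin >= 1L)
  g <- (seq_len(n) - 1L) %/% bin
  as.numeric(tapply(x, g, mean))
}

# Build a region_trace object from a per-frame series + movie metadata.
# Baseline bins are those whose frames all precede stimulation onset.
new_region_trace <- function(per_frame, frame_rate_hz, stim_onset_s,
                             region_name, bin = 3L) {
  n <- length(per_frame)
  values <- bin_by_three(per_frame, bin)
  times <- (seq_len(n) - 1L) / frame_rate_hz
  g <- (seq_len(n) - 1L) %/% bin
  bin_centers <- as.numeric(tapply(times, g, mean))
  bin_end_times <- as.numeric(tapply(times, g, max))
  baseline_bins <- which(bin_end_times < stim_onset_s)
  if (length(baseline_bins) < 1L) stop("no pre-stimulus bins in trace")
  structure(
    list(values = values,
         bin_centers_s = bin_centers,
         bin_duration_s = bin / frame_rate_hz,
         stim_onset_s = stim_onset_s,
         baseline_bins = baseline_bins,
         baseline_mean = mean(values[baseline_bins]),
         baseline_sd = stats::sd(values[baseline_bins]),
         region_name = region_name),
    class = "region_trace")
}

#' @export
print.region_trace <- function(x, ...) {
  cat(sprintf(
    "<region_trace> %s: %d bins of %.2f s, baseline %.3f +/- %.3f\n",
    x$region_name, length(x$values), x$bin_duration_s,
    x$baseline_mean, x$baseline_sd))
  invisible(x)
}

#' Mean intensity-change trace of a region
#'
#' Per-frame mean of the percent CBV change over the region's pixels,
#' averaged in 3-frame bins.
#'
#' @param response an `ois_response`.
#' @param region logical mask (non-empty, same geometry).
#' @param region_name label stored on the trace.
#' @return a `region_trace` (values in % change).
#' @export
intensity_trace <- function(response, region, region_name = "region") {
  stopifnot(inherits(response, "ois_response"),
            is.logical(region))
  d <- dim(response$pct_change)
  if (!identical(dim(region), d[1:2])) stop("region geometry mismatch")
  if (sum(region) == 0L) stop("empty region")
  X <- matrix(response$pct_change, d[1L] * d[2L], d[3L])
  per_frame <- colMeans(X[as.vector(region), , drop = FALSE])
  new_region_trace(per_frame, response$frame_rate_hz,
                   response$stim_onset_s, region_name)
}

#' Pial-artery dilation trace by pixel counting
#'
#' Quantifies vessel caliber change as the change in the number of
#' vessel-classified pixels around the selected artery. Within a
#' morphological dilation (default 3 px radius) of the artery region, a
#' pixel counts as vessel when its intensity falls below a fixed decision
#' boundary calibrated once on the baseline frames: the ISODATA
#' (Ridler-Calvard) threshold of the neighborhood's mean baseline
#' intensities — the fixed point of "midpoint of the two class means". A
#' histogram-based threshold is used because the neighborhood is bimodal
#' (vessel dark, tissue bright) but may also contain *other* dark
#' vessels, which would contaminate any artery-vs-surround summary
#' statistic; the intermeans fixed point in particular sits at the
#' half-coverage intensity of a partial-volume vessel edge, so counted
#' pixels track the geometric vessel boundary. The per-frame count is expressed
#' as percent change versus the mean baseline count and averaged in
#' 3-frame bins.
#'
#' @param movie the preprocessed intensity movie (trial-averaged,
#'   low-pass filtered [ois_movie]).
#' @param artery_region logical mask of the artery of interest
#'   (non-empty).
#' @param neighborhood_px radius of the search neighborhood around the
#'   artery (px).
#' @param region_name label stored on the trace.
#' @return a `region_trace` (values in % pixel-count change), with the
#'   calibrated `threshold` and per-frame `counts` attached as attributes.
#' @export
dilation_trace <- function(movie, artery_region, neighborhood_px = 3L,
                           region_name = "responsive_pial_artery") {
  stopifnot(inherits(movie, "ois_movie"), is.logical(artery_region))
  d <- dim(movie$frames)
  if (!identical(dim(artery_region), d[1:2])) stop("region geometry mismatch")
  if (sum(artery_region) == 0L) stop("empty artery region")
  hood <- binary_dilate(artery_region, neighborhood_px)
  nb <- movie$n_baseline_frames
  X <- matrix(movie$frames, d[1L] * d[2L], d[3L])
  base_img <- rowMeans(X[, seq_len(nb), drop = FALSE])
  thr <- isodata_threshold(base_img[as.vector(hood)])
  mv <- stats::median(base_img[as.vector(artery_region)])
  if (!(mv < thr)) {
    stop("artery is not darker than its surroundings at baseline; ",
         "cannot calibrate the pixel-count criterion")
  }
  sel <- as.vector(hood)
  counts <- colSums(X[sel, , drop = FALSE] < thr)
  base_count <- mean(counts[seq_len(nb)])
  if (base_count == 0) stop("no vessel pixels at baseline")
  per_frame <- 100 * (counts / base_count - 1)
  out <- new_region_trace(per_frame, movie$frame_rate_hz,
                          movie$stim_onset_s, region_name)
  attr(out, "threshold") <- thr
  attr(out, "counts") <- counts
  out
}

#' Response onset time of a region trace
#'
#' The onset is the first bin, searching from stimulation onset, whose
#' value strictly exceeds the baseline mean plus two baseline SDs (the SD
#' floored at `eps` so noiseless traces still have a defined onset).
#' Times are reported at bin centers, relative to stimulation onset.
#'
#' @param trace a `region_trace`.
#' @param eps floor on the baseline SD (trace units).
#' @return onset time in s, or `NA_real_` when the trace never exceeds
#'   the criterion ("no onset").
#' @export
onset_time <- function(trace, eps = 1e-6) {
  stopifnot(inherits(trace, "region_trace"))
  if (length(trace$baseline_bins) < 3L) stop("need >= 3 baseline bins")
  thr <- trace$baseline_mean + 2 * max(trace$baseline_sd, eps)
  cand <- which(trace$bin_centers_s >= trace$stim_onset_s)
  hit <- cand[trace$values[cand] > thr]
  if (length(hit) == 0L) return(NA_real_)
  trace$bin_centers_s[hit[1L]] - trace$stim_onset_s
}

#' Rising slope between onset and peak
#'
#' The incline ratio `(peak value - onset value) / (peak time - onset
#' time)` of a response trace, in trace units per second.
#'
#' @param trace a `region_trace`.
#' @param onset_s onset time (s from stimulation onset; see
#'   [onset_time()]).
#' @param peak list with `value` and `time_s` (s from stimulation onset),
#'   e.g. from [peak_metrics()]; or `NULL` to locate the peak internally.
#' @return slope in trace units / s.
#' @export
rising_slope <- function(trace, onset_s, peak = NULL) {
  stopifnot(inherits(trace, "region_trace"))
  if (is.na(onset_s)) stop("onset does not exist")
  if (is.null(peak)) peak <- trace_peak(trace)
  if (peak$time_s <= onset_s) stop("peak must come after the onset")
  onset_bin <- which(abs(trace$bin_centers_s -
                           (trace$stim_onset_s + onset_s)) < 1e-9)[1L]
  (peak$value - trace$values[onset_bin]) / (peak$time_s - onset_s)
}

# Peak of a binned trace over bins from stimulation onset to the end.
trace_peak <- function(trace) {
  cand <- which(trace$bin_centers_s >= trace$stim_onset_s)
  k <- cand[which.max(trace$values[cand])]
  list(value = trace$values[k],
       time_s = trace$bin_centers_s[k] - trace$stim_onset_s,
       bin = k)
}

#' Normalize a trace so its maximum is exactly 100
#'
#' Scales the binned values by `100 / max(values)`, used to compare the
#' dynamics (timing, shape) of regions whose absolute response amplitudes
#' differ.
#'
#' @param trace a `region_trace` with a strictly positive maximum.
#' @return the rescaled `region_trace`.
#' @export
normalize_trace_to_100 <- function(trace) {
  stopifnot(inherits(trace, "region_trace"))
  m <- max(trace$values)
  if (m <= 0) stop("trace maximum must be positive to normalize")
  f <- 100 / m
  trace$values <- trace$values * f
  trace$baseline_mean <- trace$baseline_mean * f
  trace$baseline_sd <- trace$baseline_sd * f
  trace
}

#' Peak dynamics metrics of a region trace
#'
#' Bundles the four descriptors of a response: maximum change, time to
#' peak (bin center, from stimulation onset), onset time, and rising
#' slope. The slope is `NA` when no onset exists or the peak does not
#' follow the onset (e.g. a flat trace).
#'
#' @param trace a `region_trace`.
#' @param eps baseline-SD floor for the onset criterion.
#' @return list of class `dynamics_metrics`: `max_change_pct`,
#'   `time_to_peak_s`, `onset_time_s`, `rising_slope_pct_per_s`,
#'   `region_name`.
#' @export
peak_metrics <- function(trace, eps = 1e-6) {
  stopifnot(inherits(trace, "region_trace"))
  pk <- trace_peak(trace)
  onset <- onset_time(trace, eps)
  slope <- if (!is.na(onset) && pk$time_s > onset) {
    rising_slope(trace, onset, pk)
  } else {
    NA_real_
  }
  structure(list(max_change_pct = pk$value,
                 time_to_peak_s = pk$time_s,
                 onset_time_s = onset,
                 rising_slope_pct_per_s = slope,
                 region_name = trace$region_name),
            class = "dynamics_metrics")
}

#' @export
print.dynamics_metrics <- function(x, ...) {
  cat(sprintf(
    "<dynamics_metrics> %s: max %.2f%%, ttp %.2f s, onset %s s, slope %s %%/s\n",
    x$region_name, x$max_change_pct, x$time_to_peak_s,
    ifelse(is.na(x$onset_time_s), "NA", sprintf("%.2f", x$onset_time_s)),
    ifelse(is.na(x$rising_slope_pct_per_s), "NA",
           sprintf("%.2f", x$rising_slope_pct_per_s))))
  invisible(x)
}
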