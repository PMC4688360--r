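#' Temporal standard-deviation map of a movie
#'
#' Per-pixel standard deviation of the intensity over all N frames, in the
#' population form (divisor N, not N - 1): with `PA_ij` the temporal mean
#' of pixel (i, j),
#' `sd_ij = sqrt( (1/N) * sum_k (P_ij(k) - PA_ij)^2 )`.
#' High values mark pixels whose intensity varies with the evoked
#' response; a constant movie gives an identically zero map.
#'
#' @param movie an [ois_movie] (typically the trial-averaged, low-pass
#'   filtered stack).
#' @return An object of class `sd_map`: list with `sd` (matrix >= 0),
#'   `n_frames_used`, `smoothed` (FALSE), and the pixel size.
#' @export
compute_sd_map <- function(movie) {
  stopifnot(inherits(movie, "ois_movie"))
  d <- dim(movie$frames)
  if (d[3L] < 2L) stop("need at least 2 frames")
  X <- matrix(movie$frames, d[1L] * d[2L], d[3L])
  m <- rowMeans(X)
  v <- rowMeans((X - m)^2)
  structure(list(sd = matrix(sqrt(v), d[1L], d[2L]),
                 n_frames_used = d[3L],
                 smoothed = FALSE,
                 pixel_size_mm = movie$pixel_size_mm),
            class = "sd_map")
}

#' @export
print.sd_map <- function(x, ...) {
  cat(sprintf("<sd_map> %d x %d px over %d frames (%s)\n",
              nrow(x$sd), ncol(x$sd), x$n_frames_used,
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

#' Smooth a map with a normalized 3x3 Gaussian kernel
#'
#' Convolution with a 3x3 Gaussian (sigma 0.8 px, weights summing to 1,
#' reflect-padded borders), applied to maps before thresholding so single
#' outlier pixels do not contaminate the masks. A constant map passes
#' through unchanged.
#'
#' @param map an `sd_map` or a plain numeric matrix.
#' @param sigma Gaussian sigma in pixels (default 0.8: the discrete 3x3
#'   kernel then carries >95% of the continuous mass).
#' @return The smoothed object (same type as the input; an `sd_map` gets
#'   `smoothed = TRUE`).
#' @export
smooth_map <- function(map, sigma = 0.8) {
  k <- gauss_kernel1d(sigma, radius = 1L)
  if (inherits(map, "sd_map")) {
    map$sd <- conv_sep2d(map$sd, k)
    map$smoothed <- TRUE
    map
  } else {
    stopifnot(is.matrix(map))
    conv_sep2d(map, k)
  }
}

#' Responsive-area mask from an SD map
#'
#' Thresholds the (smoothed) SD map at its own mean plus two population
#' standard deviations, computed over all map pixels; pixels *strictly*
#' above the threshold form the responsive area. Low-variation pixels are
#' thereby excluded as showing no response over time.
#'
#' @param sdmap an `sd_map` (should be smoothed first; a warning is
#'   issued otherwise).
#' @return logical mask of the responsive area.
#' @export
responsive_mask <- function(sdmap) {
  stopifnot(inherits(sdmap, "sd_map"))
  if (!sdmap$smoothed) {
    warning("SD map has not been smoothed; thresholding the raw map")
  }
  v <- as.vector(sdmap$sd)
  sdmap$sd > mean(v) + 2 * pop_sd(v)
}

#' Decompose the field of view into the four characteristic regions
#'
#' Combines the responsive-area mask with the thresholded vessel
#' probability map into: the responsive area itself; the responsive pial
#' artery (responsive AND vessel); the responsive tissue (responsive AND
#' NOT vessel); and the non-responsive vessels (vessel AND NOT
#' responsive). Thresholding the probability map and intersecting is
#' boolean-equivalent to multiplying the probability map into the mask
#' first and thresholding afterwards.
#'
#' @param responsive logical responsive-area mask.
#' @param prob_map a `vessel_prob_map`, or a logical vessel mask.
#' @param vessel_threshold probability threshold (default 0.6).
#' @return An object of class `region_masks` with the four logical masks
#'   plus `vessel` (the full vessel mask).
#' @export
decompose_regions <- function(responsive, prob_map, vessel_threshold = 0.6) {
  stopifnot(is.logical(responsive), is.matrix(responsive))
  vessel <- if (is.logical(prob_map)) {
    prob_map
  } else {
    threshold_vessels(prob_map, vessel_threshold)
  }
  if (!identical(dim(vessel), dim(responsive))) {
    stop("responsive mask and vessel map geometries differ")
  }
  structure(
    list(responsive_area = responsive,
         responsive_pial_artery = responsive & vessel,
         responsive_tissue = responsive & !vessel,
         nonresponsive_vessels = vessel & !responsive,
         vessel = vessel),
    class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf(
    paste0("<region_masks> responsive %d px | artery %d | tissue %d | ",
           "non-responsive vessels %d\n"),
    sum(x$responsive_area), sum(x$responsive_pial_artery),
    sum(x$responsive_tissue), sum(x$nonresponsive_vessels)))
  invisible(x)
}
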