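#' OIS trial movie container
#'
#' Holds a single stimulation trial: a stack of grayscale reflectance frames
#' plus the acquisition metadata the analysis needs. Frames are stored as a
#' numeric array indexed `[row, col, frame]` (1-based, row 1 = image top);
#' intensities are arbitrary non-negative units.
#'
#' Under the standard protocol (10 Hz, stimulation at 5 s) the pre-stimulus
#' baseline is the first 50 frames, i.e. `n_baseline_frames` defaults to
#' `round(stim_onset_s * frame_rate_hz)`.
#'
#' @param frames numeric array `[row, col, frame]`, finite and `>= 0`.
#' @param frame_rate_hz acquisition rate (Hz).
#' @param pixel_size_mm size of one pixel (mm). Must be supplied by the user:
#'   camera optics vary and the pixel pitch cannot be recovered from a TIFF.
#' @param stim_onset_s,stim_duration_s stimulation envelope (s); frame `k`
#'   is acquired at time `(k - 1) / frame_rate_hz`.
#' @param n_baseline_frames number of initial frames used as the baseline.
#' @return An object of class `ois_movie`.
#' @export
ois_movie <- function(frames, frame_rate_hz, pixel_size_mm,
                      stim_onset_s, stim_duration_s,
                      n_baseline_frames = round(stim_onset_s * frame_rate_hz)) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array [row, col, frame]")
  }
  if (!all(is.finite(frames))) stop("frames contain non-finite values")
  if (any(frames < 0)) stop("frames contain negative intensities")
  stopifnot(frame_rate_hz > 0, pixel_size_mm > 0,
            stim_onset_s >= 0, stim_duration_s > 0)
  n_baseline_frames <- as.integer(n_baseline_frames)
  if (n_baseline_frames < 1L || n_baseline_frames >= dim(frames)[3L]) {
    stop("n_baseline_frames must be in [1, n_frames - 1]")
  }
  structure(
    list(frames = frames,
         frame_rate_hz = frame_rate_hz,
         pixel_size_mm = pixel_size_mm,
         stim_onset_s = stim_onset_s,
         stim_duration_s = stim_duration_s,
         n_baseline_frames = n_baseline_frames),
    class = "ois_movie")
}

# Internal constructor for stacks built by the package itself, skipping the
# full-array finiteness scan of the exported constructor.
new_ois_movie <- function(frames, template) {
  structure(
    list(frames = frames,
         frame_rate_hz = template$frame_rate_hz,
         pixel_size_mm = template$pixel_size_mm,
         stim_onset_s = template$stim_onset_s,
         stim_duration_s = template$stim_duration_s,
         n_baseline_frames = template$n_baseline_frames),
    class = "ois_movie")
}

#' @export
print.ois_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ois_movie> %d x %d px, %d frames @ %g Hz (%.1f s), pixel %g mm\n",
    d[1], d[2], d[3], x$frame_rate_hz, d[3] / x$frame_rate_hz,
    x$pixel_size_mm))
  cat(sprintf("  stimulation: %g s for %g s; baseline frames: %d\n",
              x$stim_onset_s, x$stim_duration_s, x$n_baseline_frames))
  invisible(x)
}

#' @export
dim.ois_movie <- function(x) dim(x$frames)

# Frame acquisition times (s), frame 1 at t = 0.
frame_times <- function(movie) {
  (seq_len(dim(movie$frames)[3L]) - 1L) / movie$frame_rate_hz
}

#' Ordered set of repeated trials
#'
#' Bundles the repeated stimulation trials of one recording session. All
#' trials must share frame geometry and acquisition metadata (the standard
#' protocol repeats the stimulus 8 times).
#'
#' @param trials a list of [ois_movie] objects.
#' @return An object of class `trial_set` (a validated list of movies).
#' @export
trial_set <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  ok <- vapply(trials, inherits, logical(1), "ois_movie")
  if (!all(ok)) stop("all elements must be ois_movie objects")
  ref <- trials[[1L]]
  for (tr in trials[-1L]) {
    if (!identical(dim(tr$frames), dim(ref$frames))) {
      stop("trials differ in frame geometry")
    }
    meta <- c("frame_rate_hz", "pixel_size_mm", "stim_onset_s",
              "stim_duration_s", "n_baseline_frames")
    if (!isTRUE(all.equal(tr[meta], ref[meta]))) {
      stop("trials differ in acquisition metadata")
    }
  }
  structure(trials, class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials\n", length(x)))
  print(x[[1L]])
  invisible(x)
}

#' Read and write the per-dataset acquisition config
#'
#' Acquisition metadata (frame rate, pixel size, stimulation timing, the
#' intensity scale used when quantizing to 16-bit TIFF) lives in a small
#' YAML sidecar file rather than in TIFF tags, which are dialect-prone.
#'
#' @param path file path of the YAML config.
#' @param config a named list with fields `frame_rate_hz`, `pixel_size_mm`,
#'   `stim_onset_s`, `stim_duration_s`, `n_baseline_frames`,
#'   `intensity_scale`.
#' @return `read_ois_config()` returns the named list; `write_ois_config()`
#'   returns `path` invisibly.
#' @export
read_ois_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("frame_rate_hz", "pixel_size_mm", "stim_onset_s",
            "stim_duration_s", "n_baseline_frames", "intensity_scale")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  }
  cfg
}

#' @rdname read_ois_config
#' @export
write_ois_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a trial movie as a multi-page 16-bit TIFF
#'
#' Intensities are divided by `intensity_scale` (default: the stack maximum)
#' and quantized to 16 bits, one page per frame. The scale is recorded in
#' the sidecar config so that [read_trial_stack()] restores original units.
#'
#' @param movie an [ois_movie].
#' @param path output TIFF path.
#' @param config_path optional path for the YAML sidecar (default:
#'   `path` with extension replaced by `.yaml`).
#' @param intensity_scale divisor mapping intensities into `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_trial_stack <- function(movie, path, config_path = NULL,
                              intensity_scale = NULL) {
  stopifnot(inherits(movie, "ois_movie"))
  if (is.null(intensity_scale)) intensity_scale <- max(movie$frames)
  if (intensity_scale <= 0) intensity_scale <- 1
  if (max(movie$frames) > intensity_scale + 1e-12) {
    stop("intensity_scale smaller than the stack maximum")
  }
  if (is.null(config_path)) config_path <- tiff_sidecar_path(path)
  nfr <- dim(movie$frames)[3L]
  pages <- lapply(seq_len(nfr), function(k) {
    # quantize by rounding; the half-quantum offset defeats the writer's
    # truncation so stored codes are round(x * 65535)
    codes <- pmin(round(movie$frames[, , k] / intensity_scale * 65535), 65535)
    pmin((codes + 0.499) / 65535, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  write_ois_config(list(
    frame_rate_hz = movie$frame_rate_hz,
    pixel_size_mm = movie$pixel_size_mm,
    stim_onset_s = movie$stim_onset_s,
    stim_duration_s = movie$stim_duration_s,
    n_baseline_frames = movie$n_baseline_frames,
    intensity_scale = intensity_scale), config_path)
  invisible(path)
}

tiff_sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0(".yaml")
}

#' Read a trial movie from a multi-page TIFF
#'
#' Pages are taken in file order as frames; row 1 is the image top.
#' Metadata comes from the YAML sidecar config (see [write_ois_config()])
#' or from explicitly supplied arguments, which override the config.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param config a config list, or a path to a YAML config; defaults to the
#'   sidecar next to `path`.
#' @param ... metadata overrides (`frame_rate_hz`, `pixel_size_mm`, ...).
#' @return An [ois_movie].
#' @export
read_trial_stack <- function(path, config = NULL, ...) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1L) {
    stop("TIFF pages have inconsistent shapes")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse any extra channels
    p
  })
  if (is.null(config)) {
    sidecar <- tiff_sidecar_path(path)
    if (file.exists(sidecar)) config <- read_ois_config(sidecar)
  } else if (is.character(config)) {
    config <- read_ois_config(config)
  }
  overrides <- list(...)
  cfg <- utils::modifyList(if (is.null(config)) list() else config, overrides)
  need <- c("frame_rate_hz", "pixel_size_mm", "stim_onset_s",
            "stim_duration_s")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    stop("missing metadata for ", path, ": ",
         paste(missing, collapse = ", "))
  }
  scale <- if (is.null(cfg$intensity_scale)) 1 else cfg$intensity_scale
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1L]])[1:2], length(pages))) * scale
  nb <- if (is.null(cfg$n_baseline_frames)) {
    round(cfg$stim_onset_s * cfg$frame_rate_hz)
  } else {
    cfg$n_baseline_frames
  }
  ois_movie(frames, cfg$frame_rate_hz, cfg$pixel_size_mm,
            cfg$stim_onset_s, cfg$stim_duration_s, nb)
}

#' Write a mask as a 0/255 single-page image
#'
#' @param mask logical matrix.
#' @param path output path (TIFF or PNG by extension; TIFF used here).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a 0/255 mask image
#'
#' @param path mask image path.
#' @return logical matrix (`TRUE` where the stored value exceeds half range).
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' Write per-animal metric records as a CSV
#'
#' One row per animal x metric, with a stable column order
#' (`animal`, `group`, `metric`, `value`, then any extra columns) and
#' deterministic full-precision formatting.
#'
#' @param records a data.frame with at least columns `animal`, `group`,
#'   `metric`, `value`. A zero-row data.frame yields a header-only CSV.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  need <- c("animal", "group", "metric", "value")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L) {
    stop("records must carry columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(records), need)
  records <- records[, c(need, extra), drop = FALSE]
  utils::write.csv(format(records, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a metrics CSV written by [write_results_table()]
#'
#' @param path CSV path.
#' @return data.frame with `value` parsed as numeric.
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("value" %in% names(df)) df$value <- as.numeric(df$value)
  df
}
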