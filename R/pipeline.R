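#' Vascular-function analysis of one trial set
#'
#' Runs the vessel-dynamics half of the pipeline on a recording: average
#' and low-pass filter the trials; segment vessels on the baseline-mean
#' reference image with the random-forest pixel classifier; compute the
#' smoothed temporal SD map and the mean + 2 SD responsive-area mask;
#' decompose the field into the four characteristic regions; and extract
#' per-region intensity traces, the pial-artery pixel-count dilation
#' trace, and their peak/onset/slope metrics.
#'
#' Training labels come either from a user-supplied label mask or, for
#' synthetic data, from auto-scribbles sampled off the ground-truth mask
#' boundary.
#'
#' @param trials a [trial_set].
#' @param labels integer label matrix (1 vessel / 2 tissue), or `NULL` to
#'   derive auto-labels from `truth`.
#' @param truth optional `ois_truth` (required when `labels` is `NULL`).
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param vessel_threshold probability threshold for the vessel mask.
#' @param neighborhood_px dilation-trace search radius (px).
#' @param rng_seed seed for label sampling and forest training.
#' @return An object of class `vascular_analysis`: reference image,
#'   classifier, probability map, SD map, `regions` ([decompose_regions()]
#'   output), `contrast` (Michelson vessel/tissue contrast of the training
#'   labels), `traces` (named list of `region_trace`) and `metrics`
#'   (named list of `dynamics_metrics`).
#' @export
analyze_vascular <- function(trials, labels = NULL, truth = NULL,
                             cutoff_hz = 0.5, vessel_threshold = 0.6,
                             neighborhood_px = 3L, rng_seed = 1L) {
  if (!inherits(trials, "trial_set")) trials <- trial_set(trials)
  avg <- average_trials(trials)
  filt <- lowpass_filter(avg, cutoff_hz)
  nb <- filt$n_baseline_frames
  ref <- apply(filt$frames[, , seq_len(nb), drop = FALSE], c(1, 2), mean)

  if (is.null(labels)) {
    if (is.null(truth)) {
      stop("supply either a label mask or a ground truth to auto-label")
    }
    labels <- sample_training_labels(truth$vessel_mask, rng_seed = rng_seed)
  }
  feats <- extract_pixel_features(ref)
  clf <- train_classifier(feats, labels, rng_seed = rng_seed)
  prob <- predict_probability(clf, ref)
  contrast <- label_contrast(ref, labels)

  sdm <- smooth_map(compute_sd_map(filt))
  responsive <- responsive_mask(sdm)
  regions <- decompose_regions(responsive, prob, vessel_threshold)

  resp <- normalize_to_baseline(filt)
  traces <- list()
  for (nm in c("responsive_area", "responsive_pial_artery",
               "responsive_tissue")) {
    if (sum(regions[[nm]]) > 0L) {
      traces[[nm]] <- intensity_trace(resp, regions[[nm]], nm)
    }
  }
  notes <- character(0)
  # a dilation trace can be uncalibratable (e.g. the responsive artery is
  # a handful of edge pixels); record why and carry on with NA metrics
  # rather than aborting the recording
  for (spec in list(c("responsive_pial_artery", "artery_dilation"),
                    c("nonresponsive_vessels", "nonresponsive_dilation"))) {
    if (sum(regions[[spec[1L]]]) > 0L) {
      tr <- tryCatch(
        dilation_trace(filt, regions[[spec[1L]]], neighborhood_px,
                       region_name = spec[2L]),
        error = function(e) conditionMessage(e))
      if (inherits(tr, "region_trace")) {
        traces[[spec[2L]]] <- tr
      } else {
        notes <- c(notes, paste0(spec[2L], ": ", tr))
      }
    }
  }
  metrics <- lapply(traces, peak_metrics)
  structure(list(reference_image = ref, classifier = clf,
                 prob_map = prob, sd_map = sdm, regions = regions,
                 contrast = contrast, traces = traces, metrics = metrics,
                 notes = notes),
            class = "vascular_analysis")
}

#' @export
print.vascular_analysis <- function(x, ...) {
  cat("<vascular_analysis>\n")
  print(x$regions)
  cat(sprintf("  label contrast %.3f\n", x$contrast))
  for (m in x$metrics) print(m)
  invisible(x)
}

#' Measure every animal of a synthetic cohort
#'
#' Renders each animal of a [generate_cohort()] cohort in turn and runs
#' the CBV analysis (and optionally the vascular analysis), returning one
#' row per animal with the injected ground-truth parameters alongside the
#' measured metrics.
#'
#' @param cohort an `ois_cohort`.
#' @param vascular also run [analyze_vascular()] per animal (slower:
#'   trains a classifier per animal).
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param crop,side_mm CBV crop settings (see [analyze_cbv()]).
#' @param verbose print progress.
#' @return data.frame: the cohort's ground-truth table plus measured
#'   `max_cbv_pct`, `ttp_s`, `peak_extent_mm2` and, when
#'   `vascular = TRUE`, `max_dilation_pct`, `dilation_ttp_s`,
#'   `dilation_onset_s`, `dilation_slope_pct_per_s`, `contrast`.
#' @export
measure_cohort <- function(cohort, vascular = FALSE, cutoff_hz = 0.5,
                           crop = TRUE, side_mm = 3.0, verbose = FALSE) {
  stopifnot(inherits(cohort, "ois_cohort"))
  out <- cohort$animals
  out$max_cbv_pct <- NA_real_
  out$ttp_s <- NA_real_
  out$peak_extent_mm2 <- NA_real_
  if (vascular) {
    out$max_dilation_pct <- NA_real_
    out$dilation_ttp_s <- NA_real_
    out$dilation_onset_s <- NA_real_
    out$dilation_slope_pct_per_s <- NA_real_
    out$contrast <- NA_real_
  }
  for (i in seq_len(nrow(out))) {
    sim <- render_animal(cohort, i)
    cbv <- analyze_cbv(sim$trials, cutoff_hz = cutoff_hz, crop = crop,
                       side_mm = side_mm)
    out$max_cbv_pct[i] <- cbv$metrics$max_change_pct
    out$ttp_s[i] <- cbv$metrics$time_to_peak_s
    out$peak_extent_mm2[i] <- max(cbv$extent_mm2)
    if (vascular) {
      va <- analyze_vascular(sim$trials, truth = sim$truth,
                             cutoff_hz = cutoff_hz,
                             rng_seed = cohort$animals$seed[i])
      dm <- va$metrics$artery_dilation
      if (!is.null(dm)) {
        out$max_dilation_pct[i] <- dm$max_change_pct
        out$dilation_ttp_s[i] <- dm$time_to_peak_s
        out$dilation_onset_s[i] <- dm$onset_time_s
        out$dilation_slope_pct_per_s[i] <- dm$rising_slope_pct_per_s
      }
      out$contrast[i] <- va$contrast
    }
    if (verbose) {
      message(sprintf("  %s: max CBV %.2f%% (injected %.2f%%)",
                      out$animal[i], out$max_cbv_pct[i],
                      out$peak_amplitude_pct[i]))
    }
  }
  out
}

#' Summarize a measured cohort into long metric records
#'
#' Reshapes a [measure_cohort()] table into the long `animal x metric`
#' form accepted by [write_results_table()].
#'
#' @param measured data.frame from [measure_cohort()].
#' @return data.frame with columns `animal`, `group`, `metric`, `value`.
#' @export
cohort_records <- function(measured) {
  metric_cols <- setdiff(names(measured),
                         c("animal", "group", "seed"))
  do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(animal = measured$animal, group = measured$group,
               metric = mc, value = measured[[mc]],
               stringsAsFactors = FALSE)
  }))
}
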