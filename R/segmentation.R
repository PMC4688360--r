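#' Multi-scale per-pixel features for vessel classification
#'
#' Computes, for every pixel of a 2-D reference image, the 17-feature
#' multi-scale stack used by the trainable vessel/tissue classifier:
#' raw intensity; Gaussian blur at scales {1, 2, 4, 8} px; gradient
#' magnitude at each scale; and the smallest and largest eigenvalue of the
#' Hessian at each scale (a ridge detector — dark tubular structures give a
#' strongly positive largest eigenvalue). Every feature is standardized to
#' zero mean and unit variance over the image; a zero-variance feature is
#' defined as all zeros.
#'
#' @param image numeric matrix (finite values).
#' @param scales Gaussian scales in pixels.
#' @return numeric matrix `[n_pixels x n_features]` (pixels in column-major
#'   order) with a `feature_spec` attribute (data.frame of name + scale).
#' @export
extract_pixel_features <- function(image, scales = c(1, 2, 4, 8)) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  feats <- list(intensity = as.vector(image))
  spec <- data.frame(name = "intensity", scale = 0)
  for (s in scales) {
    g <- gauss_blur2d(image, s)
    gr <- grad2d(g)
    gradmag <- sqrt(gr$dr^2 + gr$dc^2)
    # Hessian from second central differences of the blurred image
    drr <- grad2d(gr$dr)$dr
    dcc <- grad2d(gr$dc)$dc
    drc <- grad2d(gr$dr)$dc
    tr2 <- (drr + dcc) / 2
    disc <- sqrt(((drr - dcc) / 2)^2 + drc^2)
    nm <- sprintf(c("blur_s%g", "grad_s%g", "hess_min_s%g", "hess_max_s%g"), s)
    feats[[nm[1L]]] <- as.vector(g)
    feats[[nm[2L]]] <- as.vector(gradmag)
    feats[[nm[3L]]] <- as.vector(tr2 - disc)
    feats[[nm[4L]]] <- as.vector(tr2 + disc)
    spec <- rbind(spec, data.frame(
      name = nm, scale = s))
  }
  out <- vapply(feats, function(f) {
    s <- stats::sd(f)
    if (s == 0) rep(0, length(f)) else (f - mean(f)) / s
  }, numeric(length(image)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  colnames(out) <- names(feats)
  attr(out, "feature_spec") <- spec
  out
}

#' Label-mask codes
#'
#' Label masks are integer matrices with 0 = unlabeled, 1 = vessel,
#' 2 = tissue, sharing the image geometry.
#'
#' @param vessel,tissue logical matrices (or index vectors) marking the
#'   labeled pixels of each class.
#' @param dim image dimensions `c(nrow, ncol)` (required when indices are
#'   given).
#' @return integer label matrix.
#' @export
label_mask <- function(vessel, tissue, dim = NULL) {
  if (is.logical(vessel) && is.matrix(vessel)) {
    dim <- base::dim(vessel)
    vessel <- which(vessel)
    tissue <- which(tissue)
  }
  stopifnot(!is.null(dim))
  lab <- matrix(0L, dim[1L], dim[2L])
  lab[vessel] <- 1L
  lab[tissue] <- 2L
  lab
}

#' Auto-generate training scribbles from a ground-truth vessel mask
#'
#' Samples confident training pixels away from the vessel boundary:
#' vessel labels from the mask eroded by `margin_px`, tissue labels from
#' the complement dilated-safe zone (`margin_px + 1` away from any
#' vessel). Used to train the classifier on synthetic scenes where the
#' true mask is known; real data would use hand-drawn label images.
#'
#' @param vessel_mask logical matrix (true vessel at rest).
#' @param n_per_class pixels to sample per class.
#' @param margin_px boundary exclusion margin (px).
#' @param rng_seed sampling seed.
#' @return integer label matrix (see [label_mask()]).
#' @export
sample_training_labels <- function(vessel_mask, n_per_class = 500L,
                                   margin_px = 1L, rng_seed = 1L) {
  stopifnot(is.logical(vessel_mask), is.matrix(vessel_mask))
  core_vessel <- binary_erode(vessel_mask, margin_px)
  core_tissue <- !binary_dilate(vessel_mask, margin_px + 1L)
  iv <- which(core_vessel)
  it <- which(core_tissue)
  if (length(iv) < 20L || length(it) < 20L) {
    stop("not enough confident pixels to sample training labels")
  }
  with_seed(rng_seed, {
    label_mask(sample(iv, min(n_per_class, length(iv))),
               sample(it, min(n_per_class, length(it))),
               dim = dim(vessel_mask))
  })
}

#' Train the vessel/tissue pixel classifier
#'
#' Fits a probability random forest (ranger; >= 100 trees, per-split
#' feature subsampling) on the labeled pixels only. Deterministic for a
#' fixed seed (single-threaded).
#'
#' @param features feature matrix from [extract_pixel_features()].
#' @param labels integer label matrix (0 unlabeled / 1 vessel / 2 tissue)
#'   with `prod(dim(labels)) == nrow(features)`.
#' @param rng_seed forest seed.
#' @param num_trees number of trees (>= 100).
#' @return An object of class `vessel_classifier`.
#' @export
train_classifier <- function(features, labels, rng_seed = 1L,
                             num_trees = 200L) {
  stopifnot(is.matrix(features), num_trees >= 100L)
  lab <- as.integer(labels)
  if (length(lab) != nrow(features)) {
    stop("labels and features disagree in pixel count")
  }
  idx <- which(lab > 0L)
  y <- factor(c("vessel", "tissue")[lab[idx]],
              levels = c("vessel", "tissue"))
  counts <- table(y)
  if (any(counts == 0L)) stop("training labels must contain both classes")
  if (any(counts < 20L)) stop("need at least 20 labeled pixels per class")
  df <- data.frame(features[idx, , drop = FALSE], .class = y,
                   check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, probability = TRUE,
    seed = as.integer(rng_seed %% .Machine$integer.max),
    num.threads = 1L, verbose = FALSE)
  structure(list(model = fit,
                 feature_spec = attr(features, "feature_spec"),
                 feature_names = colnames(features)),
            class = "vessel_classifier")
}

#' Vessel probability map for an image
#'
#' Recomputes the classifier's feature stack on `image` and returns the
#' per-pixel probability of the vessel class (fraction of tree votes).
#'
#' @param classifier a `vessel_classifier`.
#' @param image numeric matrix.
#' @return An object of class `vessel_prob_map`: list with `prob` (matrix
#'   in `[0, 1]`) and `feature_spec`.
#' @export
predict_probability <- function(classifier, image) {
  stopifnot(inherits(classifier, "vessel_classifier"))
  scales <- unique(classifier$feature_spec$scale)
  feats <- extract_pixel_features(image, scales = scales[scales > 0])
  if (!identical(colnames(feats), classifier$feature_names)) {
    stop("feature specification mismatch between training and prediction")
  }
  pred <- stats::predict(classifier$model,
                         data = data.frame(feats, check.names = FALSE),
                         num.threads = 1L, verbose = FALSE)
  prob <- pred$predictions[, "vessel"]
  structure(list(prob = matrix(prob, nrow(image), ncol(image)),
                 feature_spec = classifier$feature_spec),
            class = "vessel_prob_map")
}

#' @export
print.vessel_prob_map <- function(x, ...) {
  cat(sprintf("<vessel_prob_map> %d x %d px, mean prob %.3f\n",
              nrow(x$prob), ncol(x$prob), mean(x$prob)))
  invisible(x)
}

#' Binarize a vessel probability map
#'
#' A pixel is vessel when its probability *strictly* exceeds the
#' threshold; the 0.6 default trades detection against false positives.
#'
#' @param prob_map a `vessel_prob_map` (or plain probability matrix).
#' @param threshold probability threshold in (0, 1).
#' @return logical vessel mask.
#' @export
threshold_vessels <- function(prob_map, threshold = 0.6) {
  stopifnot(threshold > 0, threshold < 1)
  prob <- if (inherits(prob_map, "vessel_prob_map")) prob_map$prob else prob_map
  prob > threshold
}

#' Vessel/tissue contrast of labeled pixels
#'
#' Michelson contrast between the mean intensity of the labeled vessel and
#' tissue pixels, `(I_tissue - I_vessel) / (I_tissue + I_vessel)`. Low
#' contrast flags recordings where segmentation is unreliable (the
#' classic exclusion ground); the value is always reported, never used to
#' drop data silently.
#'
#' @param image numeric matrix.
#' @param labels integer label matrix (1 vessel / 2 tissue).
#' @return contrast in `[-1, 1]` (positive when vessels are darker).
#' @export
label_contrast <- function(image, labels) {
  stopifnot(identical(dim(image), dim(labels)))
  mv <- mean(image[labels == 1L])
  mt <- mean(image[labels == 2L])
  (mt - mv) / (mt + mv)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices.
#' @return IoU in `[0, 1]` (1 if both are empty).
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
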