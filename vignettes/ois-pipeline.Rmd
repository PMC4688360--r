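---
title: "Evoked CBV and pial-artery dynamics from optical intrinsic signal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked CBV and pial-artery dynamics from optical intrinsic signal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oisr)
```

## The measurement and its model

Optical intrinsic signal (OIS) imaging records the reflectance of the
exposed cortical surface under narrow-band illumination. At the 570 nm
hemoglobin isosbestic wavelength, oxy- and deoxyhemoglobin absorb equally,
so reflectance changes track *total* hemoglobin — a proxy for cerebral
blood volume (CBV) — independent of oxygenation. A functional recruitment
of blood to active cortex therefore appears as a localized *darkening* of
the image. The package analyses the standard stimulus-evoked protocol:
repeated trials of 200 frames at 10 Hz (20 s), with the stimulus delivered
5 s after acquisition onset for 5 s, and the first 50 frames (5 s) serving
as the pre-stimulus baseline.

The CBV half of the pipeline is a chain of simple, exactly specified
steps:

1. **Trial averaging** — the frame-wise arithmetic mean of the repeated
   trials, improving SNR by roughly the square root of the trial count.
2. **Temporal low-pass filtering** — every pixel's time series is filtered
   with a zero-phase (forward–backward) 4th-order Butterworth low-pass
   filter with unit DC gain. Spatial content is untouched.
3. **Baseline division** — each frame is divided by the per-pixel mean of
   the baseline frames; under the reflectance convention the sign is
   flipped so that a CBV increase is a positive percent change.
4. **Cropping** — the analysis is restricted to a 3 × 3 mm window around
   the activation (side length rounded to the nearest odd pixel count).
   Because steps 1–3 act pixel-wise in time, cropping commutes exactly
   with them; the implementation crops first and filters only the window.
5. **ROI metrics** — a 7 × 7 pixel region of interest is selected
   automatically; its mean trace yields the maximum CBV change and the
   time-to-peak, computed on a centered 3-frame moving average
   (truncated at the record ends), with the peak searched from
   stimulation onset to the end of the recording and ties resolved to the
   earliest frame. The activation extent is the per-frame area of pixels
   whose change strictly exceeds 1.0%.

The vascular half characterizes the vessels themselves:

1. **Vessel segmentation** — a trainable pixel classifier (a probability
   random forest over a 17-feature multi-scale stack: raw intensity,
   Gaussian blurs, gradient magnitudes, and both Hessian eigenvalues at
   scales 1, 2, 4 and 8 px, each standardized over the image) produces a
   per-pixel vessel probability, binarized at a strict 0.6 threshold.
   The reference image is the temporal mean of the baseline frames of
   the averaged movie — the highest-SNR frame free of stimulus
   contamination.
2. **SD map and responsive area** — the per-pixel temporal standard
   deviation of the preprocessed movie over all N frames, in the
   *population* form (divisor N), smoothed with a normalized 3 × 3
   Gaussian kernel; pixels strictly above the map's own mean + 2
   population SDs form the responsive area.
3. **Four-region decomposition** — responsive area, responsive pial
   artery (responsive ∧ vessel), responsive tissue (responsive ∧ ¬vessel)
   and non-responsive vessels (vessel ∧ ¬responsive). Thresholding the
   probability map and intersecting is boolean-equivalent to multiplying
   the probability map into the mask first and thresholding afterwards.
4. **Dynamics** — per-region traces are averaged in non-overlapping
   3-frame bins (0.3 s at 10 Hz; a final partial bin averages its actual
   frames). Artery caliber is quantified by *pixel counting*: within a
   3-px morphological dilation of the artery region, pixels darker than a
   baseline-calibrated boundary are counted per frame and expressed as
   percent change versus the baseline count. Each trace is summarized by
   its maximum, time-to-peak (bin centers, from stimulation onset), onset
   (first post-stimulus bin strictly exceeding baseline mean + 2 baseline
   SD) and rising slope ((peak − onset value)/(peak − onset time)).
   Traces can be rescaled so their maximum is exactly 100 to compare
   timing across regions of different amplitude.

Group comparisons use the two-sided Mann–Whitney rank-sum test (exact for
small tie-free samples), the independent t-test (Welch by default, pooled
by request), per-bin Mann–Whitney tests for frame-wise significance
shading (unadjusted by default, matching common practice; an optional
Benjamini–Hochberg flag is provided and labelled), and one-way ANOVA with
Fisher LSD post-hoc tests built from the pooled mean-square error.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff_hz` | 0.5 | Hz | Passes the ~0.1–0.3 Hz evoked response (two-pass gain ≈ 0.999 at 0.2 Hz) while rejecting respiratory (~1 Hz under anesthesia) and cardiac bands. A cutoff *at* the respiration frequency would only half-attenuate it — a zero-phase Butterworth has |H|² = 0.5 at its cutoff — and the residual oscillation measurably jitters peak-latency estimates; hence the default sits below the physiological bands rather than at them. Configurable. |
| `n_baseline_frames` | `stim_onset_s × frame_rate_hz` (50) | frames | The full pre-stimulus epoch. |
| ROI `size` | 7 | px | The window whose mean of per-pixel temporal maxima is maximized; ties go to the smallest (row, col). |
| `threshold_pct` | 1.0 | % | Activation-extent threshold; strictly greater-than. |
| `vessel_threshold` | 0.6 | probability | Detection/false-positive trade-off for the vessel mask; strict inequality. |
| SD-map smoothing σ | 0.8 | px | The discrete 3 × 3 kernel then carries > 95% of the continuous Gaussian mass. |
| `neighborhood_px` | 3 | px | Dilation-trace search radius around the artery; bounds the count region without retraining the classifier per frame. |
| onset ε | 1e-6 | trace units | Floor on the baseline SD so noiseless traces still have a defined onset. |

## The synthetic-data generator

Real recordings of this kind are rarely deposited, so the package ships a
generator whose defaults *are* the study conditions: 200 frames at 10 Hz,
stimulation at 5 s for 5 s, 8 trials, and two cohort presets —
**control** (peak CBV change 4.02%, time-to-peak 4.65 s, artery dilation
6.48%) and **stress** (1.82%, 5.43 s, 3.49%), with between-animal SDs
recovered from reported standard errors via SD = SEM·√n (n = 10 for the
CBV metrics; n = 6 and 5 for dilation).

Each synthetic animal consists of:

* a **branching pial vessel tree** — two or more artery trunks entering
  from the image border with children at 0.65× the parent width, plus
  wider non-dilating veins (veins are rendered because large dark
  non-responsive structures are a real feature of the field of view);
  vessels are rasterized with 1-px linear partial-volume edges;
* a **gamma-variate response kernel** rising from stimulation onset and
  peaking at the configured time-to-peak (shape 3, giving a fall over
  roughly 5 s; the decay is a free simulator parameter — published traces
  constrain the rise much better than the fall), normalized so its
  maximum on the frame grid is exactly 1;
* an **amplitude map** with a uniform core of the configured peak change
  within `footprint_radius_mm` (default 0.75 mm), cosine-tapered to zero
  by 1.5× the radius — uniform so that a 7 × 7 ROI inside the footprint
  measures the injected amplitude rather than a taper average;
* **artery dilation**: segments whose midpoint falls inside the response
  footprint are re-rendered every frame with their width scaled by
  `1 + dilation_pct/100 ×` kernel;
* **noise**: per-pixel additive white noise (default SD 0.2% of the local
  baseline) plus global sinusoids (defaults: 1 Hz at 0.2% "respiration",
  4 Hz at 0.1% "cardiac alias") with independent random phases per trial.

Every pixel's noiseless trace is exactly
`baseline × (1 − amplitude/100 × kernel[t])`, with a CBV increase rendered
as a reflectance decrease; the analysis layer flips the sign back.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: photon transport and wavelength-dependent
path length; oxy/deoxy spectral mixing away from the isosbestic point;
motion and pulsation artifacts beyond global intensity oscillations;
spatially correlated physiological noise (vasomotion); irregular vessel
cross-sections and diameter-dependent absorbance saturation. Recovery
results on synthetic data demonstrate that the *computational chain* is
unbiased and stable at realistic SNR, not that the biological estimates
are accurate in vivo.

## Numerical choices

* **Zero-phase filtering** uses steady-state initial conditions and
  mirror-reflection end padding of 15 × (filter length − 1) samples.
  Mirror (rather than odd, `2x₀ − x`) padding keeps the pad at the
  signal's own level, so the reverse pass re-enters the data without a
  step transient when a record ends mid-oscillation; the generous pad
  length covers the slowly decaying poles of narrow-band designs.
* **SD maps** use divisor N (population form), and the responsive-area
  threshold likewise uses the population SD of the map, keeping the two
  conventions consistent. The SD map is computed on the trial-averaged,
  low-pass-filtered movie over all 200 frames (configurable), matching
  the CBV pipeline's preprocessing.
* **Dilation-trace calibration**: the vessel/non-vessel intensity
  boundary is the ISODATA (Ridler–Calvard) threshold of the
  neighborhood's mean-baseline intensities. The intermeans fixed point
  sits at the half-coverage intensity of a partial-volume edge, so pixel
  counts track the geometric vessel boundary; summary statistics of
  "artery vs surround" were rejected because the neighborhood of a
  responsive artery frequently contains *other* dark vessels. The
  strategy is swappable (`dilation_trace()` is independent of the
  classifier).
* **Tie-breaks**: ROI selection resolves ties to the smallest
  (row, col); peak searches resolve ties to the earliest frame/bin.
* **Degenerate inputs**: a constant movie yields an identically zero
  response and an empty responsive mask; a zero or negative baseline
  pixel is an explicit error naming the pixel, never a silent NaN;
  zero-variance features standardize to zero; a zero-noise baseline gets
  an ε floor so onsets remain defined.
* **Quantization**: 16-bit TIFF output rounds to the nearest code (with
  a half-quantum offset defeating the writer's truncation) and records
  the intensity scale in a YAML sidecar, so round trips are exact for
  pre-quantized data.

## Design decisions where the procedure was genuinely open

* **ROI objective** — "automatically selected" is realized as the window
  maximizing the mean of per-pixel temporal maxima over the
  stimulation-to-end epoch, matching the reporting of a *maximum* CBV
  change; documented and swappable.
* **Time-to-peak reference** — measured from stimulation onset, the
  convention consistent with reported values of ~4.7 s for a 5-s
  stimulus in a 20-s recording.
* **Classifier features and labels** — the exact trainable-segmentation
  feature set behind published pixel classifiers is tool-specific; the
  17-feature blur/edge/ridge family above captures the standard
  defaults. Training scribbles are sampled off the ground-truth mask
  boundary for synthetic scenes (margin 1 px); real data would use
  hand-drawn label images. A Michelson vessel/tissue contrast of the
  labelled pixels is always reported so that low-contrast recordings can
  be excluded explicitly, never silently.
* **Pixel-count dilation** within a 3-px neighborhood (rather than
  re-running the classifier per frame, or sub-pixel FWHM fitting) keeps
  the per-frame decision identical across the trial and bounds the
  search region; FWHM-style caliber estimation is noted as a future
  strategy.
* **Cohort rendering is lazy** — `generate_cohort()` returns the
  ground-truth parameter table and per-animal seeds; stacks are rendered
  on demand by `render_animal()`, since a full 20-animal cohort of
  8-trial stacks would hold ~0.6 GB even at small fields of view.

## Problem sizes used by the validation suite

The test-suite and acceptance studies choose fields of view by purpose:
full 128 × 128 px scenes (0.05 mm/px) for amplitude/timing recovery and
dilation benchmarks; 96 × 96 px scenes for segmentation fixtures; and
32 × 32 px (0.11 mm/px) for the 200-cohort power/level study, where only
the ROI statistics are needed and the temporal protocol — the part that
matters for those statistics — is kept at full size (200 frames, 8
trials). The pixel pitch is not a protocol constant (it depends on the
camera and optics, which is also why `pixel_size_mm` is mandatory user
input), so spatial scale is the one knob traded against replicate count.

## Known limitations

* Vessel-edge partial-volume transients during strong dilation can leak
  into the CBV amplitude of windows containing large arteries; the
  amplitude-recovery benchmark therefore isolates the parenchymal field
  (dilation 0), and measured cohort amplitudes sit slightly above the
  injected group means when dilation is large. This mirrors the physical
  reality that vessel caliber changes *are* part of the reflectance
  signal.
* Pixel counting quantizes caliber: a 2% width change of a 6-px vessel
  moves the boundary by 0.06 px and is detected only through
  partial-volume edge pixels, so short artery segments yield noisy
  dilation estimates at the smallest effect sizes.
* The frame-wise significance shading is intentionally unadjusted for
  multiplicity (the common practice it reproduces); the BH option should
  be preferred for confirmatory claims.
* Onset times are reported at 0.3-s bin centers; latencies finer than
  the bin width are not resolvable by construction.
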