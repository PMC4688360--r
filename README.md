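# oisr

Analysis of stimulus-evoked **optical intrinsic signal (OIS)** recordings
of the cortical surface, for experimenters quantifying how cerebral blood
volume (CBV) and pial-artery caliber respond to sensory stimulation —
e.g. comparing hemodynamic reactivity between treatment groups.

At the 570 nm hemoglobin isosbestic wavelength, cortical reflectance
tracks total hemoglobin, so a local CBV increase appears as a darkening
of the image. Given repeated stimulation trials (multi-page TIFF stacks
with a small YAML sidecar holding frame rate, pixel size and stimulus
timing), the package computes:

* **CBV response maps** — trials are averaged, each pixel is low-pass
  filtered with a zero-phase Butterworth filter, and frames are divided
  by the pre-stimulus baseline:
  `ΔCBV(t, i, j) [%] = −100 · (I(t, i, j) / B(i, j) − 1)`,
  with `B` the per-pixel mean of the first 50 frames (the − sign flips
  the reflectance convention so CBV increases are positive).
* **ROI metrics** — an automatically selected 7 × 7 px region of
  interest yields the maximum CBV change and time-to-peak (3-frame
  moving average, peak searched from stimulation onset), plus the
  activation extent (area with ΔCBV > 1.0%).
* **Vessel segmentation** — a trainable random-forest pixel classifier
  over a 17-feature multi-scale stack (intensity, Gaussian blurs,
  gradient magnitudes, Hessian eigenvalues at scales 1–8 px) gives a
  vessel probability map, binarized at 0.6.
* **Responsive-area detection** — the per-pixel temporal standard
  deviation over all N frames (population form,
  `SD(i,j) = sqrt((1/N) Σₖ (P(i,j,k) − P̄(i,j))²)`), smoothed with a
  3 × 3 Gaussian and thresholded at its own mean + 2 SD.
* **Four-region decomposition** — responsive area, responsive pial
  artery, responsive tissue, non-responsive vessels.
* **Vascular dynamics** — pixel-count dilation traces and per-region
  intensity traces in 3-frame bins, summarized by maximum, time-to-peak,
  onset (baseline mean + 2 SD criterion) and rising slope.
* **Group statistics** — Mann–Whitney and t-tests with mean ± SEM
  summaries, frame-wise significance shading, and one-way ANOVA with
  Fisher LSD post-hoc tests.

Because raw recordings of this kind are rarely shared, the package also
ships a **synthetic OIS generator** with full ground truth — branching
vessel trees, a gamma-variate hemodynamic kernel, stimulus-locked artery
dilation, white noise and physiological oscillations — whose defaults
encode a two-group (control vs chronically stressed) study design. Every
quantitative claim in the test suite is validated against this ground
truth or an independent brute-force oracle.

## Worked example

```r
library(oisr)

params <- scenario_params(preset = "control", rng_seed = 42)  # 128x128 px, 8 trials
sim    <- simulate_animal(params)      # vessel tree + ground truth + trials

cbv <- analyze_cbv(sim$trials)         # average -> filter -> baseline -> crop -> ROI
print(cbv)
#> <cbv_analysis> max CBV change 6.86%, time-to-peak 4.70 s, peak extent 3.283 mm^2
print(cbv$roi)
#> <roi_selection> 7x7 at (row 24, col 30), score 6.860%

vasc <- analyze_vascular(sim$trials, truth = sim$truth, rng_seed = 42)
print(vasc$metrics$artery_dilation)
#> <dynamics_metrics> artery_dilation: max 5.27%, ttp 3.80 s, onset 0.80 s, slope 1.70 %/s
```

Reading the output: the injected parenchymal response peaks at 4.02%
4.65 s after stimulus onset; the measured time-to-peak (4.70 s) lands on
the nearest frame. The ROI maximum (6.86%) exceeds the parenchymal
amplitude because the window also catches the reflectance transient of
the dilating feeding artery — caliber change is part of the optical
signal (with `dilation_pct = 0` the pipeline recovers the injected
amplitude to within a few hundredths of a percentage point). The
artery's pixel count rises by 5.27% at its peak, with onset 0.8 s after
the stimulus.

A two-group in-silico study:

```r
ctrl <- scenario_params(preset = "control", image_height_px = 64L,
                        image_width_px = 64L, pixel_size_mm = 0.055)
strs <- scenario_params(preset = "stress",  image_height_px = 64L,
                        image_width_px = 64L, pixel_size_mm = 0.055)
cohort   <- generate_cohort(ctrl, strs, n_per_group = 10, rng_seed = 1)
measured <- measure_cohort(cohort, vascular = TRUE)
amp <- split(measured$max_cbv_pct, measured$group)
compare_groups(amp$control, amp$stress, metric_name = "max_cbv_pct",
               group_names = c("control", "stress"))
```

A thin command-line front end mirroring these steps lives at
`inst/cli/ois.R` (subcommands `simulate`, `analyze-cbv`, `segment`,
`regions`, `dynamics`, `compare`).

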