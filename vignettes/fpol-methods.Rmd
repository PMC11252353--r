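---
title: "Methods: automated Fpol quantification of thyroid cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Fpol quantification of thyroid cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific background

Methylene blue (MB) accumulates differently in malignant and benign
thyroid cells, and the *fluorescence polarization* (Fpol) of its emission
is higher in malignant cells. Measuring Fpol per cell in fine-needle
aspirate (FNA) smears therefore offers a quantitative adjunct to visual
cytopathology, particularly for indeterminate specimens.

Fpol is computed from a pair of images of the same field: the co-polarized
channel \(I_{co}\) (emission parallel to the excitation polarization) and
the cross-polarized channel \(I_{cross}\):

\[
\mathrm{Fpol} = \frac{I_{co} - G\, I_{cross}}{I_{co} + G\, I_{cross}}
\]

where \(G\) is an instrument calibration factor correcting polarization
bias of the detection path. The package default is `FPOL_G_DEFAULT = 0.75`.

The analysis bottleneck is cell selection: an expert must outline
diagnostically usable cells in every field. This package automates that
step with a semantic segmentation network and reproduces the downstream
quantification and statistics, so that automated (AU) and manual (MA)
analyses can be compared cell by cell.

## Pipeline model

1. **Input**: an 8-bit co/cross image pair (`read_pair()`), default pixel
   size 0.205 µm/px (`PIXEL_SIZE_DEFAULT`, a 205 µm field over 1000 px).
2. **Segmentation** (`predict_pair()`): a 5-level encoder–decoder (U-Net)
   with two input channels (co, cross scaled to [0, 1]) and three output
   classes — background, *ambiguous* cell-like signal, and *high-quality*
   cells (the expert-selected, diagnostically relevant class). Softmax
   probabilities per pixel.
3. **Post-processing** (`postprocess_probability()`): the high-quality
   probability map is binarized at 0.5, dilated (3×3 square, 3
   iterations), eroded (same, 3 iterations), opened with a 15×15
   elliptical element, and labeled into 8-connected components.
4. **Quantification** (`quantify_sample()`): per labeled cell, pixel and
   physical area and Fpol computed from channel means over *valid*
   pixels.
5. **Comparison** (`match_cells()`, `compare_sample()`): AU and MA
   regions are paired by pixel overlap and per-pair percent differences
   reported.
6. **Statistics** (`run_group_stats()`): group means ± SD by method and
   diagnosis, two-tailed t-tests with Bonferroni correction at
   family-wise α = 0.01.

`run_pipeline()` orchestrates all stages over a CSV manifest and writes
per-sample cell tables, a group summary, a JSON test report, and a run
log. A command-line front end with one subcommand per stage is installed
at `system.file("cli", "fpolcyto.R", package = "fpolcyto")`.

## Numerical and algorithmic choices

These choices are deliberate and tested; several resolve ambiguities that
any reimplementation must decide one way or the other.

- **Binarization tie rule.** A pixel with probability exactly 0.5 is
  foreground (`binarize()` uses ≥). A strict `>` would silently empty
  masks produced by argmax ties.
- **Morphology dialect.** Structuring elements are centered and odd-sized;
  pixels outside the image are background for both dilation and erosion.
  The 15×15 opening element is the filled ellipse
  \((\Delta y/7)^2 + (\Delta x/7)^2 \le 1\). These match the common
  computer-vision convention; note that some image-analysis libraries
  instead treat the border as foreground during erosion, which changes
  results at image edges. The implementation is verified bit-exactly
  against brute-force set-definition oracles in the test suite.
- **Connectivity.** Connected components are 8-connected by default
  (diagonal contact joins regions); labels are assigned in raster order
  of each region's first pixel so ids are deterministic.
- **Valid-pixel band.** A pixel contributes to a cell's intensity means
  only if *both* channels lie in [3, 254]: values below are noise-floor,
  254–255 indicate saturation, and Fpol is a ratio so an invalid value in
  either channel invalidates the pixel. Cells with fewer than 50 % valid
  pixels are retained in the table with `quality_flag = "excluded"`
  rather than dropped, so counts stay auditable.
- **Fpol of means.** Cell Fpol is computed from the *means* of the two
  channels (ratio of summed intensities), not the mean of per-pixel Fpol
  values. The two agree for uniform cells but differ under noise because
  Fpol is a nonlinear ratio; `method = "mean_of_fpol"` exposes the
  alternative.
- **Reporting precision.** Percent differences use the symmetric form
  \(100(a-b)/\tfrac{a+b}{2}\) (`pct_diff()`) and are rounded to one
  decimal *half away from zero* (`round_half_out()`); base R's
  round-half-even would disagree on ties such as 15.75.
- **Statistical design.** Between-diagnosis contrasts (malignant vs
  benign, malignant vs normal) use unpaired pooled-variance Student
  t-tests — the cells in different diagnosis groups are different cells
  and cannot be paired. The AU-vs-MA contrast uses a paired test on
  matched cells (`pair_id`). The Bonferroni family is all comparisons in
  one run (six in the standard layout). Single-cell groups report SD 0
  with a warning instead of failing.
- **Matching rule.** Greedy one-to-one matching by descending pixel
  overlap; a pair is accepted only if the overlap exceeds half of the
  *smaller* region's area. Ties break deterministically by smaller AU
  id, then MA id.

## Network and training

The network is a standard U-Net implemented natively in R: 3×3
same-padding convolutions via im2col and BLAS matrix multiplication,
ReLU, 2×2 max-pooling, 2×2 stride-2 transposed-convolution upsampling
with skip concatenation, a 1×1 output head, softmax cross-entropy with
equal class weights, hand-derived backpropagation, and Adam. Gradients
are verified against finite differences in the test suite.

Training defaults (`train_config()`): 30 epochs, batch size 4, learning
rate 1e-3, random crops of 64 px with online augmentation — rotation
±180°, horizontal/vertical flips, scaling 0.8–1.2, shear ±10°. **Elastic
deformation is implemented but disabled by default** (`elastic = FALSE`):
published descriptions of this training recipe are internally
inconsistent about its use, so the conservative default is off and the
option is explicit. Input sizes must be divisible by \(2^{levels-1}\);
the package errors and asks you to pad or crop rather than resampling
implicitly.

Problem sizes are deliberately *desk scale*: the package's reference
experiment trains a 5-level, base-16-channel network on twenty 128×128
phantoms in a few minutes on one CPU and reaches Dice ≥ 0.8 for the
high-quality class on held-out noiseless phantoms. Full-resolution
(1000×1000, long-schedule) training is outside the scope of a CPU-only
test suite; inference at 1000×1000 is supported and fast.

## Phantoms and their limits

`generate_phantom()` renders seeded synthetic co/cross pairs with exact
ground truth: elliptical cells with a smooth radial intensity profile,
per-cell target Fpol values (defaults span 0.10–0.33, the clinically
observed range), optional clustered placement, dimmer blurred
*ambiguous* objects, Gaussian noise, and 8-bit quantization. The cross
channel is derived by inverting the Fpol formula per pixel,
\(I_{cross} = I_{co}(1-f)/(G(1+f))\), so ground-truth Fpol is exact by
construction; quantization bounds the round-trip error below 0.01, and
disabling quantization (`quantize = FALSE`) makes it exact to machine
precision.

Phantoms are a verification instrument, not a simulation of cytology:
real FNA smears have textured chromatin, overlapping cells, debris, and
spatially varying background that the generator does not attempt. Real
clinical Fpol values reported for MB-stained thyroid FNA samples are
used only as plausibility bounds on the generator's defaults, since the
underlying images are not redistributable.

## Reproducibility

Every stochastic component (phantom generation, weight initialization,
augmentation, shuffling) is governed by an explicit seed in its config
object, and RNG state is saved and restored so package calls do not
perturb the caller's random stream. Fixed config + fixed checkpoint
gives bit-identical pipeline outputs.
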