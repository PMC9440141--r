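---
title: "Methods: supervised denoising of volumetric neuro-imaging data"
author: "niddl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised denoising of volumetric neuro-imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, generators, numerical conventions and
design decisions behind `niddl`, in the spirit of a methods section: what
is computed, under which assumptions, and what the shipped tests do and do
not establish.

## Problem setting

Volumetric fluorescence recordings of neuronal activity (nucleus-localized
calcium indicators in *C. elegans* head ganglia, ventral-cord motor
neurons, or neurite-labeled mechanosensory neurons) are photon-limited:
exposure time and laser power are capped by the volume rate and by
photobleaching. The package fits a supervised denoiser on pairs of low-SNR
and high-SNR acquisitions of *independent, immobilized* samples — not
video frames — and applies it to each volume of a video independently.
Because training needs only two images per sample, no ultrafast imaging,
no temporal registration and no per-recording retraining are required.

## Architectures

All four families share one U-shaped macro-layout: a stem convolution, 4
scales of encoder blocks separated by 2×2 max-pooling, a bottleneck, a
mirrored decoder with 2× upsampling, and a linear 3×3 head. A
*convolutional block* is two k×k convolutions (k = 3 by default, 5
optional), each followed by ReLU; in `hourglass_wres` the block input is
added to the pre-activation output (an identity short-range residual,
possible only because channel depth is constant). No normalization layers
are used anywhere, and the head is linear so outputs are unconstrained.

The two *fixed-channel* families hold every feature map at 32 channels.
The parameter budget this frees is spent on depth, concentrated at coarse
scales where convolutions are cheap and receptive-field growth per block
is largest: 2/4/8/10 blocks at scales 0–3, with 3 bottleneck blocks for
`unet_fixed` and 1 for `hourglass_wres` (whose skip paths carry trainable
side convolutions instead). Skip merging is by concatenation plus a 1×1
fusion convolution in the U-Net family, and by summation after a 3×3 side
convolution in the hourglass family. Upsampling is nearest-neighbour
followed by a 3×3 convolution in the U-Net family and a learned 2×2
stride-2 transposed convolution in the hourglass family; the asymmetry is
deliberate — summation-merged decoders pair naturally with learned
upsampling, and with these block tables the two optimized models land at
exactly 989,217 and 960,417 trainable parameters, i.e. 3.77 MB and
3.66 MB at 4 bytes/parameter, the sizes the package's accounting reports.
The exact layer tables are constructed in `build_graph()` (R/arch.R) and
are covered by tests.

The doubling-channel variants (`unet`, `hourglass_wores`) use the
conventional one block per scale with channels 32→512; they exist as size
and accuracy baselines (≈13× and ≈11× larger than their fixed
counterparts).

Weight initialization is uniform fan-in (`±sqrt(6/fan_in)`), biases zero —
hence a fresh model maps zero input to zero output — and is fully
determined by the seed.

### Input modes

- **2d** — one plane in, one plane out. The default and the recommended
  mode: planes of a volume are denoised independently.
- **2p5d** — the plane plus `context_d` z-neighbours above and below enter
  as channels; the centre plane is predicted. At stack borders, missing
  neighbours are replaced by the nearest existing plane at inference time;
  during training only interior planes are sampled.
- **3d** — consecutive `context_d`-plane chunks with 3×3×3 convolutions;
  pooling stays in-plane (depths of 1–2 planes leave nothing to pool
  axially).

## Training

Adam (learning rate 0.001, conventional β = 0.9/0.999), batch size,
epoch count and epoch size (samples drawn per epoch) are free parameters
with defaults of 50/100/1000; desk-scale analyses in the tests reduce
them, never the other way around. Every sample — input and target — is
min–max normalized per image before entering the network, because low- and
high-laser-power acquisitions live on very different intensity scales; the
same rule is applied at inference, using the noisy input's own range, and
inverted afterwards so outputs live on the input's scale. Validation
splits are assigned by whole stack (never by plane) to avoid z-plane
leakage; the returned model carries the parameters of the best validation
epoch. Planes larger than 512 pixels per side are trained on random
256×256 crops and denoised in 256-pixel tiles with 32-pixel overlapping
margins that are centre-cropped away.

Numerically the engine computes in single precision (the standard
precision for CNN training) through one batched C++ pass per optimizer
step; an independent layer-by-layer R implementation of the same graphs is
kept in the package and the tests assert that both routes agree, and that
every linear kernel satisfies its adjoint identity exactly. Training is
bytewise reproducible given the seed.

## Synthetic data generators

The generators serve two purposes: study conditions for the shipped
evaluations, and ground truth that real recordings cannot provide.

**Nucleus scenes.** Cells are 3D Gaussian intensity profiles. Centres are
drawn uniformly in the ellipsoid inscribed in the stack (a head-region
stand-in) with a minimum separation of 3 voxels by rejection; sizes are
anisotropic covariances with lateral σ ∈ [1.5, 3] and axial σ ∈ [1, 2]
voxels under a random rotation; relative peaks are uniform in [0.3, 1].
The summed image is affinely rescaled to [0, photon_level]. The defaults
for full scenes are 60 cells in 128×128×30 voxels across photon levels
{20, 50, 100, 200, 500, 1000}; the desk-scale training images used by the
test suite are 64×64 single planes with 8 cells — the same areal cell
density as a typical plane through the full scene.

**Noise.** `corrupt()` draws, per voxel, `Poisson(clean)` plus
`Normal(0, 1)` readout noise. There are no other free parameters; the
clean value *is* the Poisson rate, so "photon level" is the peak photon
count. Expectation is preserved and the variance at constant signal λ is
λ + 1, which the tests verify empirically.

**Semi-synthetic videos.** Frame t renders the same nucleus set with cell
i's peak multiplied by trace value y(i, t). Traces are baseline 0.2 plus a
Poisson number (rate 0.03/frame) of transients with instantaneous rise,
amplitude 0.8 and exponential decay τ = 8 frames — a generative stand-in
for sampled experimental recordings that keeps the features that matter
for recovery tests (sparse onsets, indicator-timescale decay); real
GCaMP traces additionally carry baseline drift and correlated dynamics
that this model does not emulate. All frames are rescaled *jointly*
(global max/min across frames, the documented rule; per-frame rescaling
exists behind a flag for sensitivity checks), then corrupted per frame.
Ground-truth traces are read from the clean video at the rounded cell
centres, i.e. in post-rescale intensity units. Cell positions may also be
supplied from a CSV atlas (`cell_id,x,y,z`); the internal sampler is the
default so nothing external is required. Full-scale defaults are 130
cells, 512×512×30, 100 frames, photon levels {100, 200, 500, 1000}; the
desk-scale video in the tests is 30 cells, 128×128×16, 50 frames at
photon level 200.

**Neurite phantoms.** Branched piecewise-smooth curves (a trunk crossing
the field plus random side branches) deposited at unit mass per unit arc
length and blurred with a σ = 1 px Gaussian — a ≈2-pixel tube whose
cross-section integral equals √(2π)σ per unit length, the oracle the
tests use. The true centreline mask is returned. No claim is made that
the phantom reproduces real neurite morphology; it exists to give the
segmentation pipeline a known answer.

## Metrics

RMSE, PSNR and SSIM are computed after min–max normalizing *both* images
independently (so all three are invariant to affine intensity transforms
of either image). PSNR is capped at 100 dB for exact equality. SSIM uses a
7×7 Gaussian window (σ = 1.5), k1 = 0.01, k2 = 0.03, data range 1; 3D
stacks are scored per plane and averaged, matching how 2D images are
counted in accuracy tables. Trace accuracy is per-cell MAE and Pearson
correlation against the ground-truth-video traces; correlations of
zero-variance traces are reported missing rather than imputed.

Image SNR is estimated as mean(foreground) / background noise SD with an
Otsu foreground split; the background SD uses the scaled median absolute
deviation, a robust estimator chosen because dim sub-threshold structure
otherwise inflates the noise floor and destroys the expected monotone
growth of SNR with photon level. The whole estimator is a declared
convention — nothing in the underlying protocol pins a formula — and is
labeled as such in reports.

## Downstream analyses

**Segmentation and traces.** Nuclei are segmented by a weighted Gaussian
mixture over foreground-voxel coordinates (weights ∝ intensity; EM with a
small covariance regularizer), with the component count initialized from
the number of smoothed local intensity maxima and refined by BIC over
±20% of that count. mclust-style EM was not used directly because
per-observation weights are needed. Tracking is greedy nearest-neighbour
linking with a displacement gate (default 5 voxels/frame), a declared
convenience: on synthetic data the generator's ground-truth tracks are the
canonical source, and following the artifact-free-comparison rule the
*same* positions/masks are used to extract traces from noisy, clean and
denoised videos. Extraction is single-pixel at the rounded centre or a
mean over an odd-sided ROI box (3×5×5 z–y–x for whole-brain stacks, 1×3×3
for 2D projections).

**Curvature coupling.** The ventral-cord backbone is a least-squares
degree-4 polynomial fit of (x(s), y(s)) against a monotone arc parameter —
the normalized x-rank by default (valid while the cord does not fold back
in x; a chord-length parameterization is available) — sampled at 100
points with tangent angles atan2(y′, x′). Traces are cross-correlated
with local tangent angles by Pearson correlation at integer lags within
±10 frames (an explicit convention; the lag window is configurable), and
a recording is summarized by the maximum absolute local peak correlation
across cells.

**Neurite segmentation.** Five parameterized steps: unsharp-mask
sharpening (radius 2, amount 1); adaptive thresholding against the local
mean over a 25-pixel window plus an offset that defaults to 3× the robust
scale (MAD) of the local residual — so pure noise stays sub-threshold,
which is what makes noisy low-photon images yield next to no detections —
and is floored at zero because fluorescence is nonnegative (without the
floor, the negative ring that unsharp masking creates around bright
structures lets blank background exceed its local mean);
morphological *opening* with a 3-pixel diamond
brush (the erosion-based noise-removal step; opening rather than bare
erosion keeps thin tubes intact and makes the operation idempotent, so
re-segmenting a mask returns it unchanged); filling of holes ≤ 20 px in
the complement; removal of components < 50 px. All parameters are exposed;
the defaults are declared choices, not inferences of any published
protocol's unpublished values.

## Shipped evaluations and their scope

The test suite's end-to-end blocks run at desk scale on one CPU:

- *Restoration ordering*: `unet_fixed` (2d, L1) trained on 200 synthetic
  64×64 pairs at photon level 200 for 200 optimizer steps (batch 8, well
  under the 2000-step cap); on 50 held-out pairs the median RMSE ordering
  is denoised < best median filter < noisy.
- *Trace recovery*: the same trained network denoises a 128×128×16×50
  semi-synthetic video (30 cells, photon level 200); with shared
  ground-truth positions, denoised traces beat noisy traces in median
  per-cell correlation and MAE, and the pairwise-correlation matrix moves
  closer (Frobenius) to the ground-truth one.
- *Segmentation rescue*: a compact fixed-channel network trained on
  photon-level-50 neurite phantoms (L2 loss, the choice favoured for
  neurite data) yields strictly higher centreline recall on denoised than
  on noisy phantoms; the noiseless phantom is segmented with recall ≥ 0.9.

Passing these establishes that the implementation behaves as designed on
data drawn from its own generative model. It does not establish accuracy
on real recordings: real data carry optics (PSF), motion, bleaching,
background autofluorescence and non-Gaussian cell shapes that the
generators deliberately omit (PSF and motion simulation are out of scope).

## Known limitations

- CPU-only; large videos are denoised at roughly 0.2 s per 128×128 plane
  on a desktop core. Tiled inference keeps memory constant.
- NLM/BM3D comparisons are not implemented; only hooks for external
  implementations exist, and the in-package classical baselines are the
  median (3/5/7) and Gaussian (σ = 1/3/5) filter sweeps.
- The nearest-neighbour tracker handles immobilized-animal jitter, not
  crawling locomotion; freely-moving analyses should supply external
  tracks.
- 3D mode supports the small chunk depths it was designed for (1–2
  planes); it uses markedly more memory per sample and, consistent with
  the design rationale, is not the default.
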