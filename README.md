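# niddl: supervised deep denoising for volumetric fluorescence neuro-imaging

Volumetric calcium imaging trades off signal-to-noise ratio against imaging
speed, laser power and field of view: capturing neural dynamics at several
volumes per second in *C. elegans* forces short exposures and low laser
power, and the resulting shot- and readout-noise corrupts every downstream
analysis — nuclei segmentation, cell tracking, activity-trace extraction,
neurite morphometry. `niddl` implements a supervised deep-denoising
pipeline for this setting: compact fixed-channel encoder–decoder
convolutional networks are trained on *small* sets of temporally
independent noisy/clean image pairs (low vs. high laser power acquisitions
of immobilized animals — no video, no registration, no ultrafast imaging)
and then applied frame-independently to calcium-imaging videos.

The package is aimed at labs running confocal/spinning-disk volumetric
recordings who want high-SNR calcium traces without custom optics or GPUs:
the networks are small enough (≈1M parameters, under 4 MB) to train and
run on a CPU, and the entire training/inference engine ships inside the
package (RcppArmadillo kernels; no external deep-learning framework).

## The model

A denoiser is a function `f_θ : noisy plane → clean plane` fitted by
stochastic gradient descent (Adam, learning rate 0.001) on min–max
normalized pairs, minimizing either

- L1 loss  `mean |f_θ(x) − y|`  (default; more stable across training
  runs), or
- L2 loss  `mean (f_θ(x) − y)²`,

where `x` is the low-SNR and `y` the co-registered high-SNR image. Four
architecture families are provided, all U-shaped with 4 rounds of 2×2
max-pooling/upsampling and 3×3 convolutions:

| family            | channels      | skip paths                  | size    |
|-------------------|---------------|-----------------------------|---------|
| `unet`            | 32 → 512 doubling | concatenation           | 47.90 MB |
| `unet_fixed`      | 32 everywhere | concatenation + 1×1 fusion  | **3.77 MB** |
| `hourglass_wores` | 32 → 512 doubling | side conv, summation    | 41.59 MB |
| `hourglass_wres`  | 32 everywhere | side conv, summation, short residuals | **3.66 MB** |

Fixing the channel depth at 32 shrinks the models by an order of magnitude,
which in turn allows many more convolutional blocks per scale
(2/4/8/10 two-conv blocks at scales 0–3) and, for the hourglass, identity
residual connections inside every block. Inputs can be single planes (2D
mode), a plane plus its z-neighbours (2.5D), or small 3D chunks (3D mode
with 3D convolutions).

The noise model used by the synthetic generators is the physical one for
EMCCD detection: per-voxel `Poisson(signal) + Normal(0, 1)` — photon shot
noise whose variance equals the expected photon count, plus unit-variance
Gaussian readout noise. Image accuracy is quantified by RMSE, PSNR and SSIM
after per-image min–max normalization; trace accuracy by the per-cell mean
absolute error `MAE_i = (1/T) Σ_t |y_{i,t} − y_gt,i,t|` and Pearson
correlation against traces from the ground-truth video.

## Worked example

```r
library(niddl)

# 40 training pairs: synthetic nucleus scenes at peak 200 photons,
# corrupted by Poisson shot noise + unit readout noise
pairs <- lapply(1:40, function(i) {
  s <- make_nuclei_scene(c(1, 64, 64), n_cells = 8, photon_level = 200,
                         seed = i)
  list(clean = unclass(s$clean),
       noisy = unclass(corrupt(s$clean, seed = 1000 + i)))
})

fit <- niddl(pairs, arch = arch_spec("unet_fixed"), loss = "l1",
             epochs = 5, epoch_size = 320, batch_size = 8, seed = 7)
print(fit)
#> niddl denoiser
#>   call: niddl(pairs = pairs, arch = arch_spec("unet_fixed"), loss = "l1",
#>     epochs = 5, epoch_size = 320, batch_size = 8, seed = 7)
#>   architecture: unet_fixed (2d, 989,217 parameters, 3.77 MB)
#>   epochs: 5, final train l1 loss: 0.00372
#>   best validation RMSE: 0.01052 (normalized units)

# held-out scene: the network clearly beats the classical filter sweep
s <- make_nuclei_scene(c(1, 64, 64), n_cells = 8, photon_level = 200,
                       seed = 999)
noisy <- unclass(corrupt(s$clean, seed = 1999))
rmse(noisy, s$clean)                           # 0.0188  (raw noisy)
best_baseline(noisy, s$clean, "median")$rmse   # 0.0182  (best median filter)
rmse(predict(fit, noisy), s$clean)             # 0.0100  (denoised)
```

The printed numbers are normalized RMSE to the clean reference: lower is
better, and the fitted network improves on the best median-filter setting,
which in turn improves on the raw noisy image. `predict()` accepts planes,
stacks `(z, y, x)` and videos `(t, z, y, x)`; videos are denoised frame by
frame, after which `segment_nuclei_gmm()`, `track_nearest()`,
`extract_single_pixel()`/`extract_roi()`, `trace_mae()`/`trace_pearson()`,
`pairwise_corr()` and `pca_traces()` carry the trace-level analysis, and
`fit_backbone()`/`activity_curvature_xcorr()` and `segment_neurites()`
cover the curvature-coupling and neurite-morphology applications. A thin
command-line front end is installed at `inst/exec/niddl`
(`simulate` / `train` / `denoise` / `evaluate` / `model-info` /
`benchmark` / `trace-recovery`).

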