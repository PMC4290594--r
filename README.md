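# lopdwi

Spiral gradient sampling and voxel-wise low-pass denoising of
diffusion-weighted MRI in the **gradient direction domain**, with the
digital phantom, regularized Q-ball reconstruction and evaluation metrics
needed to validate the approach end to end.

## The problem and the method

High angular resolution diffusion imaging (HARDI) acquires, per voxel, the
attenuation `E(b, d_n)/E0` along many unit gradient directions `d_n` at
fixed `b = γ²G²δ²(Δ − δ/3)`. Thermal noise corrupts every direction
independently and biases fiber-orientation estimates. Averaging repeats is
accurate but slow; spatial filtering blurs edges.

If the directions are ordered along a continuous spherical spiral, the
per-voxel signal `s = (s_1, …, s_N)`, `s_n = E(b, d_n)/E0`, becomes a
smooth pseudo-periodic 1D signal whose diffusion content concentrates at
low discrete-Fourier frequencies, while noise is white. Denoising is then
a purely voxel-wise 1D operation:

1. order the samples by the spiral acquisition index;
2. subtract the least-squares linear trend;
3. keep only the lowest-frequency DFT bins (default cutoff 11, i.e. 21 of
   82 complex bins ≈ 25%) and zero-fill the rest;
4. restore the trend and clip negative samples.

The package implements this filter together with everything around it:

- **Schemes** — the analytically exact equal-arc-length spherical spiral
  (antipodally symmetric; 164 points reduce to an 82-direction hemisphere
  spiral), an uneven fixed-azimuth-step spiral, and electrostatic-repulsion
  even sampling, plus uniformity metrics and FSL `bvec`/`bval` I/O.
- **Phantom** — crossing-fiber digital phantoms with a two-compartment
  stick + zeppelin white-matter signal model and Rician noise at
  prescribed SNR.
- **Reconstruction** — Laplace–Beltrami-regularized Q-ball imaging
  (spherical harmonics order 8, analytic Funk–Radon transform
  `c'_lm = 2π P_l(0) c_lm`, regularization 0.006), peak extraction on an
  icosphere (≤ 3 peaks/voxel), and a log-linear diffusion-tensor fit.
- **Evaluation** — MSE against ground truth, angular error
  `(180/π)·arccos|p_gt·p_est|` with greedy one-to-one peak matching,
  fiber-count success/over/under rates, SNR estimation with median-Otsu
  background masks, paired t-tests.

## Worked example

```r
library(lopdwi)

# 82-direction hemisphere spiral from a 164-point antipodally symmetric set
scheme <- to_hemisphere(generate_exact_spiral(164, turns = "auto", bvalue = 1000))
print(scheme)
#> Gradient scheme (exact_spiral): 82 directions, 0 b0, b = 1000 s/mm^2
uniformity_metrics(scheme)
#> Uniformity: min pairwise angle 8.11 deg, energy 12312.86, max consecutive step 15.64 deg

# crossing-fiber phantom, noise-free signal, Rician noise at SNR 20
gt    <- build_ground_truth(evaluation_phantom_spec())
print(gt)
#> Phantom ground truth: 16x16x16 grid, 2176 tissue voxels (1468 fiber: 940/528)
truth <- simulate_signal(gt, scheme)
noisy <- add_rician_noise(truth, snr = 20, seed = 42)

# gradient-direction-domain denoising and its effect on signal error
denoised <- denoise_volume(noisy)
#> denoise_volume: cutoff 11, 4096 voxels, 0.004% samples clipped
dom <- array(gt$domain, gt$dim)
mse_raw <- mse_map(noisy, truth, dom); mse_lop <- mse_map(denoised, truth, dom)
paired <- paired_ttest(mse_lop$per_voxel, mse_raw$per_voxel)
#> mean MSE: raw 0.00243 -> denoised 0.00136 (paired p < 1e-300, n = 2176 voxels)

# Q-ball reconstruction of the denoised data
fib   <- array(gt$n_fibers > 0, gt$dim)
peaks <- qball_peaks(denoised, mask = fib)
fiber_count_rates(peaks, gt)
#> Fiber counts over 1468 voxels: success 91.3%, over 1.4%, under 7.2%
angular_error(gt, peaks)$mean
#> 6.51  (degrees)
```

At SNR 20 and b = 1000 s/mm², denoising roughly halves the mean squared
error to the noise-free signal; more than 90% of fiber voxels then have
the correct fiber count, with the residual under-estimation coming mostly
from the phantom's deliberately sub-resolution 45° crossing site. The
methods vignette (`vignettes/lop-dwi-methods.Rmd`) explains the model,
every tunable parameter, and the orientation-dependence of the filter
passband that governs when denoising helps.

## Command-line interface

```sh
Rscript inst/cli/lopdwi.R scheme   --kind exact-spiral --n 164 --hemisphere --b 1000 --out sch
Rscript inst/cli/lopdwi.R simulate --phantom evaluation --scheme sch.scheme --b 1000 --snr 20 --seed 5 --out phm
Rscript inst/cli/lopdwi.R denoise  --in phm.nii.gz --bval phm.bval --bvec phm.bvec --out phm_lop
Rscript inst/cli/lopdwi.R recon    --in phm_lop.nii.gz --bval phm_lop.bval --bvec phm_lop.bvec --out phm_lop
```

Every run writes a JSON manifest with the arguments and seed needed to
reproduce it.

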