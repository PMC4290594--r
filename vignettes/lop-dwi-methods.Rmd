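---
title: "Spiral sampling and low-pass denoising of diffusion MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiral sampling and low-pass denoising of diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lopdwi)
```

## The idea

High angular resolution diffusion imaging (HARDI) measures, in every voxel,
the signal attenuation $E(b, \mathbf{d}_n)/E_0$ for many gradient directions
$\mathbf{d}_n$ on the unit sphere at fixed diffusion weighting
$b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$. Directions are axes: the
signal is antipodally symmetric, $E(b,\mathbf{d}) = E(b,-\mathbf{d})$.

If the directions are acquired *in order along a continuous spherical
spiral*, the per-voxel signal
$\mathbf{s} = (s_1, \dots, s_N)$, $s_n = E(b, \mathbf{d}_n)/E_0$, is a
smooth, pseudo-periodic 1D signal in what we call the *gradient direction
domain*: consecutive samples correspond to nearby axes, so
$s_n \approx s_{n+1}$, and the diffusion signal concentrates in the
low-frequency part of the discrete Fourier spectrum while thermal noise is
spread over all frequencies. Denoising then reduces to a voxel-wise 1D
operation: subtract the least-squares linear trend, zero-fill all but the
lowest-frequency DFT bins, restore the trend, and clip negative samples.
There is deliberately no spatial coupling of any kind.

## Gradient schemes

`generate_exact_spiral(n_total, turns)` places points at equal arc length
along the spherical spiral $\theta \in [0, \pi]$, $\phi = c\,\theta$ with
$c = 2 \cdot \text{turns}$. The arc length
$s(\theta) = \int_0^\theta \sqrt{1 + c^2 \sin^2 t}\; dt$ is computed by
adaptive quadrature and inverted by root finding; the closed-form
elliptic-integral inversion would give the same points to machine precision
and the equal-arc-length property test covers the substitution. With
`turns = "auto"`, $\text{turns} = \mathrm{round}(\sqrt{n \pi}/2)$, which
equates the spacing along the spiral with the spacing between adjacent
turns and hence gives near-uniform density (the uniformity test, not the
constant itself, is the contract: the hemisphere scheme's symmetrized
Coulomb energy is within 5% of an electrostatic-repulsion scheme of the
same size).

Because the signal lives on axes, a full-sphere scheme is redundant. The
generator builds the point set antipodally symmetric by construction
($n/2$ equal-arc points from pole to equator plus their exact antipodes in
reverse spiral order), so `to_hemisphere()` — canonicalize every axis to
$z > 0$ (ties at $z = 0$ broken by $x > 0$, then $y > 0$) and collapse
duplicates, keeping the earlier acquisition index — reduces 164 generated
points to exactly 82 acquired directions forming a contiguous pole-to-equator
spiral. Consecutive-step metrics are antipodally symmetrized
($\arccos|\mathbf{d}_i \cdot \mathbf{d}_j|$): the equator junction between
the two half-spirals is a 180° azimuth jump between *antipodal* axes, i.e.
a zero-length step on axes.

Two comparison schemes are provided: `generate_uneven_spiral()` (fixed
azimuth step, default 20°, polar angle linear in the sample index from pole
to equator — whether the original in-house scheme swept linearly in
$\theta$ or in $z$ is not determinable, and linear-in-$\theta$ was chosen)
and `generate_electrostatic()` (antipodally symmetrized Coulomb-energy
minimization with inverse-square pairwise forces, tangential projection,
decaying step size with energy-increase rejection, 1000 iterations, seeded
random start; the technique's original publication does not fix these
constants).

## The filter

`filter_config()` has three knobs:

* `cutoff` (default **11**): the number of retained nonnegative-frequency
  DFT bins *including DC*. For $N = 82$ this keeps $21$ of $82$ complex
  bins ($\approx 25\%$) — this bin-counting convention is what makes
  "cutoff 11" and "about 25% of components" mutually consistent, and it is
  recorded here because other conventions exist.
* `detrend` (default TRUE): handle the pole-to-equator trend of the spiral
  signal.
* `clip_negative` (default TRUE): magnitude MR signals are nonnegative.

The implementation computes the least-squares projection of $\mathbf{s}$
onto $\mathrm{span}\{1, n, \text{in-band Fourier modes}\}$ rather than
literally detrending, masking the DFT, and re-adding the trend. The two
differ only by the small trend component that the sequential version
re-introduces through the filtered residual (order $10^{-6}$ for typical
signals), and the projection form is exactly linear and exactly idempotent,
which the sequential form is not. With `detrend = FALSE` it reduces exactly
to the DFT mask (`fourier_lowpass()`), which is tested against a direct
$O(N^2)$ DFT oracle. The trend is restored after filtering — filtering
denoises the detrended signal, it does not remove the trend — and clipping
is exposed because neither choice is forced by the method.

`denoise_volume()` applies the filter to every (masked) voxel
independently, ordered by the scheme's `order_index`; b0 frames pass
through untouched. Electrostatic schemes are refused: they have no
acquisition continuity, and inventing a re-ordering would silently change
the method.

## The digital phantom

The synthetic-data generator emulates a multi-bundle white-matter phantom:
straight cylindrical bundles in a spherical domain, rasterized on an
isotropic grid. A voxel inside $k$ bundles receives the $k$ local
centerline tangents as fiber directions with equal volume fractions (at
most 3 kept). The per-fiber signal is the two-compartment stick + zeppelin
model

$$
E/E_0 = \sum_i f_i \left[\nu\, e^{-b \lambda_\parallel (\mathbf{d}\cdot\mathbf{u}_i)^2}
 + (1-\nu)\, e^{-b(\lambda_\perp + (\lambda_\parallel-\lambda_\perp)(\mathbf{d}\cdot\mathbf{u}_i)^2)}\right]
 + \left(1 - \sum_i f_i\right) e^{-b D_{\mathrm{iso}}},
$$

with defaults $\nu = 0.4$, $\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 0.3\times10^{-3}$, $D_{\mathrm{iso}} = 3.0\times10^{-3}$
mm²/s — standard white-matter literature values, all exposed. Rician noise
at a prescribed SNR replaces each sample $s$ by
$\sqrt{(s+n_1)^2 + n_2^2}$, $n_i \sim \mathcal N(0, \sigma^2)$,
$\sigma = S_0/\mathrm{SNR}$ with $S_0 = 1$ (SNR is defined against the
unweighted signal; the convention matters and is stated here because the
mean diffusion-weighted signal is several times smaller).

Three stock geometries:

* `crossing_phantom_spec()` — three concurrent bundles through the grid
  center with pairwise crossing angles 90°/60°/45° on a 16³ grid; the
  geometry-oracle unit tests use it because it exercises 1-, 2- and
  3-fiber voxels in one configuration.
* `evaluation_phantom_spec()` — six bundles forming three *spatially
  separated* crossing sites (90°, 75°, and a small 45° site), each crossing
  pair lying in a plane containing the spiral pole axis. This is the
  geometry used by the denoising/reconstruction benchmark tests and the
  acceptance script; the rationale is below.
* `spherical27_phantom_spec()` — a deterministic 27-chord spherical
  configuration at larger scale, available for heavier experiments.

What the phantom does **not** model: curved-bundle torsion, intra-voxel
orientation dispersion, restricted-diffusion cylinder physics, membrane
permeability / spin exchange, T2/TE effects, or spatially correlated
physiological noise. Passing tests therefore demonstrate the method's
behavior under idealized sharp fiber signals, not its performance on
scanner data.

## Orientation dependence, and why the benchmark geometry is polar

The spiral covers the hemisphere in about 5.5 azimuthal revolutions, most
of whose samples lie near the equator (about 22 samples per revolution
there). Signal structure of azimuthal order $m$ near the equator therefore
appears near DFT bin $\approx 3.7\,m$: order $m = 2$ falls inside the
default passband, $m \ge 4$ falls outside it. Two consequences, both
verified by direct experiment in the test suite's development and visible
in the acceptance results:

* A 90° crossing *in the equatorial plane* has pure $m = 4$ azimuthal
  signature and is destroyed by the filter, while the same crossing in a
  plane containing the pole survives at both b-values (as does 75°; 60°
  survives at b = 3000 only; 45° is below the Q-ball resolution limit
  everywhere).
* Sharp stick signals at mid-latitude orientations carry 7–30% of their
  detrended energy above the passband, so filtering distorts them by
  roughly $10^{-3}$ in MSE regardless of noise level.

The benchmark geometry places its crossings in polar planes and keeps the
sub-resolution 45° site small, so that fiber-count under-estimation is
driven by noise rather than by geometry — consistent with the observation
that a credible multi-bundle phantom yields under-estimation rates that
never exceed about 11%. The distortion floor, however, is intrinsic:
filter-induced distortion exceeds the residual noise power above roughly
SNR 40, so the mean-MSE benefit of denoising is confined to low SNR in
this phantom, and the test suite reports exactly that (improvement with
paired $p < 10^{-10}$ at SNR 10–30 for b = 1000 and SNR 10 for b = 3000;
reversal above). Likewise the Q-ball baseline on these clean straight-bundle
signals is robust enough that angular errors sit at 3–7° even at SNR 10,
leaving little headroom for the filter to improve them. Both behaviors are
asserted as measured; neither should be extrapolated to phantoms with
dispersed, curved fiber populations.

## Reconstruction

`sh_design_matrix()` builds the real, symmetric (even-degree) modified
spherical-harmonic basis, orthonormal on the sphere
($R = (L+1)(L+2)/2$ functions; 45 at order 8), with associated Legendre
polynomials from `pracma::legendre` (MATLAB convention; the
Condon–Shortley phase only flips basis-function signs and does not affect
orthonormality). `fit_sh_regularized()` solves
$(B^\top B + \lambda L)^{-1} B^\top s$ with the Laplace–Beltrami penalty
$L = \mathrm{diag}(l^2(l+1)^2)$; $\lambda = 0.006$ is the standard
regularization for order-8 Q-ball. `qball_frt()` is the analytic
Funk–Radon transform $c'_{lm} = 2\pi P_l(0)\, c_{lm}$, cross-checked
against direct great-circle quadrature.

Peaks are extracted on a subdivided icosahedron (3 subdivisions, 642
vertices; antipodally symmetric) as strict local maxima over the triangle
neighborhood graph, thresholded at 0.1 of the min–max normalized ODF,
greedily selected by amplitude with a 25° minimum separation, at most 3
per voxel. The 0.1 threshold originates from spherical-deconvolution
practice and is reused here as the closest established value; whether to
min–max normalize before thresholding is a tooling convention with no
single standard. Both are therefore explicit configuration, with the
stated values as defaults, and `min_separation = 25°` is likewise a
convention, not a derived constant. A constant ODF has no strict local maxima and yields zero peaks by
design (such voxels count as under-estimation, not as angular errors).

`fit_dti()` is the standard log-linear tensor fit (needs ≥ 6 noncollinear
directions plus a b0), with FA from the normalized eigenvalue variance;
it exists to reproduce FA-based masking (FA > 0.7, principal eigenvector
within 20° of a chosen axis — the tolerance is ours, none being stated).

## Evaluation metrics

* **MSE**: per voxel, mean over directions of the squared difference to
  the noise-free signal; summarized over non-background voxels.
* **Angular error**: per ground-truth fiber,
  $(180/\pi) \arccos|\mathbf{p}_{gt} \cdot \mathbf{p}_{est}|$ to the
  closest estimated peak under greedy one-to-one matching (the absolute
  value encodes antipodal symmetry, so errors lie in [0°, 90°]); voxel
  value is the mean over its ground-truth fibers; voxels with zero
  estimated peaks are excluded here and counted as under-estimation.
  One-to-one matching (no reuse of an estimated peak) was chosen over
  nearest-with-reuse; with reuse, a single merged peak would count twice
  at moderate error instead of once plus an under-estimation, which
  double-rewards peak merging.
* **Count rates**: success / over- / under-estimation as percentages of
  fiber-containing voxels with estimated count equal / above / below the
  true count; they sum to 100 by construction. An angular-tolerance
  success criterion would break that identity and is deliberately not the
  default.
* **SNR**: per direction, ROI mean divided by background SD, with
  median-Otsu foreground and a 1-voxel-eroded complement as background.
* **Paired t-test** with an explicit zero-variance flag (identical inputs
  give $t = 0, p = 1$; constant nonzero differences give an undefined
  $p$, flagged rather than fabricated).

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run the full study at desk
scale: 16³ voxels, 82 directions, two b-values × six SNR levels × two
pipelines (24 Q-ball reconstructions over ~1,500 fiber voxels each),
which completes in about a minute. Key numeric choices: spiral inversion
to $10^{-13}$ (uniroot); SH systems solved by Cholesky-backed `solve`
with the regularized normal matrix; DFT equivalence asserted at
$10^{-10}$; detrend orthogonality at $10^{-9}$; duplicate-axis collapse
at $10^{-8}$ chord tolerance; hemisphere tie-breaks as described above so
no axis is ever represented twice.

## Known limitations

* The passband/orientation interaction described above is intrinsic to
  the 1D spiral parameterization with a fixed isotropic cutoff.
* The filter assumes the acquisition order is the spiral order; datasets
  acquired with even (electrostatic) schemes cannot be processed without
  an explicit re-ordering, which the tool refuses to invent.
* The phantom's sharp stick signals make both the distortion floor and
  the reconstruction baseline conservative relative to dispersed real
  tissue.
* Human-scanner effects (motion, eddy currents, EPI distortion) are out
  of scope; inputs are assumed pre-corrected.
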