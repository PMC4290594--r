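Package: lopdwi
Title: Spiral Gradient Sampling and Low-Pass Denoising of Diffusion MRI in the Gradient Direction Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for denoising high angular resolution diffusion-weighted
    MRI (HARDI) acquired along a periodic spherical spiral of gradient
    directions. When gradient directions are ordered along a continuous
    spiral on the unit sphere, the per-voxel diffusion-weighted signal is
    pseudo-periodic and concentrates at low frequencies, so thermal noise
    can be removed by detrending followed by Fourier low-pass filtering in
    the gradient direction domain. The package generates exact-spiral,
    uneven-spiral and electrostatic gradient schemes; simulates crossing
    fiber digital phantoms with a two-compartment (stick and zeppelin)
    white matter signal model under Rician noise; reconstructs fiber
    orientation distributions with Laplace-Beltrami regularized Q-ball
    imaging and extracts fiber peaks; fits the diffusion tensor; and
    evaluates denoising by mean squared error, angular error, fiber-count
    rates and SNR estimation with Otsu background masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
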