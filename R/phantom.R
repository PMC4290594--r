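#' Acquisition parameters
#'
#' Holds the Stejskal-Tanner pulse parameters from which the diffusion
#' weighting derives: `b = gamma^2 G^2 delta^2 (Delta - delta/3)` with
#' diffusion time `Delta` (s), pulse length `delta` (s), gyromagnetic ratio
#' `gamma` (rad s^-1 T^-1) and gradient strength `G` (T/mm). `S0` is the
#' unweighted signal (convention 1.0).
#'
#' @param b b-value in s/mm^2 (may be `NULL` if pulse parameters are given).
#' @param Delta,delta,gamma,G pulse parameters (see above).
#' @param S0 unweighted signal level.
#' @return A list of class `acquisition_params`.
#' @export
acquisition_params <- function(b = NULL, Delta = NULL, delta = NULL,
                               gamma = 2.6751e8, G = NULL, S0 = 1.0) {
  if (!is.null(b) && b < 0) .stopf("b must be >= 0")
  structure(list(b = b, Delta = Delta, delta = delta, gamma = gamma, G = G,
                 S0 = S0),
            class = "acquisition_params")
}

#' b-value from pulse parameters
#'
#' Stejskal-Tanner relation `b = gamma^2 G^2 delta^2 (Delta - delta/3)`.
#' Units: gamma in rad s^-1 T^-1, G in T/mm, delta and Delta in s, giving b
#' in s/mm^2.
#'
#' @param acq an [acquisition_params()] with `Delta`, `delta`, `gamma`, `G`.
#' @return b-value in s/mm^2.
#' @export
bvalue_from_pulse <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (is.null(acq$Delta) || is.null(acq$delta) || is.null(acq$G))
    .stopf("Delta, delta and G must be set")
  if (acq$delta >= acq$Delta)
    message("pulse length delta >= diffusion time Delta; check parameters")
  acq$gamma^2 * acq$G^2 * acq$delta^2 * (acq$Delta - acq$delta / 3)
}

#' Fiber bundle description
#'
#' A cylindrical bundle around a polyline centerline. Per-bundle tissue
#' parameters follow the two-compartment (stick + zeppelin) white matter
#' model: an intra-axonal stick of fraction `intra_fraction` with diffusivity
#' `lambda_par` along the fiber and zero across it, and an extra-axonal
#' axially symmetric tensor (zeppelin) with diffusivities `lambda_par` /
#' `lambda_perp`.
#'
#' @param centerline numeric matrix, K x 3 control points in mm (K >= 2).
#' @param radius bundle radius in mm.
#' @param intra_fraction intra-axonal volume fraction, in \[0, 1\].
#' @param lambda_par,lambda_perp parallel / perpendicular diffusivities in
#'   mm^2/s; `lambda_par >= lambda_perp > 0`.
#' @return A list of class `fiber_bundle`.
#' @export
fiber_bundle <- function(centerline, radius, intra_fraction = 0.4,
                         lambda_par = 1.7e-3, lambda_perp = 0.3e-3) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    .stopf("centerline must be a K x 3 matrix with K >= 2")
  if (radius <= 0) .stopf("radius must be positive")
  if (intra_fraction < 0 || intra_fraction > 1)
    .stopf("intra_fraction must be in [0, 1]")
  if (!(lambda_par >= lambda_perp && lambda_perp > 0))
    .stopf("need lambda_par >= lambda_perp > 0")
  structure(list(centerline = centerline, radius = radius,
                 intra_fraction = intra_fraction, lambda_par = lambda_par,
                 lambda_perp = lambda_perp),
            class = "fiber_bundle")
}

#' Phantom specification
#'
#' Geometry of a digital crossing-fiber phantom: an isotropic voxel grid
#' centered on the origin, a spherical tissue domain, and a list of
#' [fiber_bundle()]s. Voxels inside the domain but outside every bundle are
#' free-diffusion tissue with diffusivity `iso_diffusivity`; voxels outside
#' the domain are background (zero signal).
#'
#' @param grid_shape integer length-3 vector of voxel counts.
#' @param voxel_size isotropic voxel edge in mm.
#' @param domain_radius radius of the spherical tissue domain in mm.
#' @param bundles list of [fiber_bundle()].
#' @param iso_diffusivity free-diffusion coefficient in mm^2/s.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16, 16, 16), voxel_size = 1,
                         domain_radius = NULL, bundles,
                         iso_diffusivity = 3.0e-3) {
  if (missing(bundles) || length(bundles) == 0)
    .stopf("at least one fiber bundle is required")
  stopifnot(all(vapply(bundles, inherits, logical(1), "fiber_bundle")))
  grid_shape <- as.integer(grid_shape)
  if (is.null(domain_radius))
    domain_radius <- max(grid_shape) * voxel_size / 2
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 domain_radius = domain_radius, bundles = bundles,
                 iso_diffusivity = iso_diffusivity),
            class = "phantom_spec")
}

#' Default crossing-fiber test phantom
#'
#' Three straight bundles through the grid center with pairwise crossing
#' angles of 90, 60 and 45 degrees: bundle A along x, bundle B in the xy
#' plane at 60 degrees to A, and bundle C at 45 degrees to A and 90 degrees
#' to B. The geometry produces 1-, 2- and 3-fiber voxels at desk scale.
#'
#' @param grid_shape voxel counts (default 16^3).
#' @param voxel_size voxel edge, mm.
#' @param radius bundle radius, mm.
#' @param ... forwarded to [fiber_bundle()] (tissue parameters).
#' @return A [phantom_spec()].
#' @export
crossing_phantom_spec <- function(grid_shape = c(16, 16, 16), voxel_size = 1,
                                  radius = 4, ...) {
  ext <- max(grid_shape) * voxel_size        # long enough to span the grid
  uA <- c(1, 0, 0)
  uB <- c(cos(pi / 3), sin(pi / 3), 0)
  # uC: 45 deg to A, 90 deg to B  => solve uC . uA = cos45, uC . uB = 0
  cx <- cos(pi / 4)
  cy <- (0 - cx * uB[1]) / uB[2]
  cz <- sqrt(max(0, 1 - cx^2 - cy^2))
  uC <- c(cx, cy, cz)
  mk <- function(u) fiber_bundle(rbind(-ext * u, ext * u), radius = radius, ...)
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
               bundles = list(mk(uA), mk(uB), mk(uC)))
}

#' Evaluation phantom: separated crossing sites in polar planes
#'
#' Six straight bundles forming three spatially separated crossing sites
#' with crossing angles spanning 45 to 90 degrees: a 90 degree crossing
#' (bundles along x and z), a 75 degree crossing and a small 45 degree
#' crossing, each pair lying in a plane containing the spiral pole axis (z).
#' This layout emulates a white-matter phantom in which most fiber voxels
#' are single-population, crossing regions are a modest fraction, and -- per
#' the known behavior of Q-ball imaging -- under-estimation of fiber number
#' at high SNR comes only from the small low-angle (45 degree) crossing
#' region rather than dominating the voxel population.
#'
#' @param grid_shape voxel counts (default 16^3).
#' @param voxel_size voxel edge, mm.
#' @param radius radius of the main-site bundles, mm (the 45 degree site
#'   uses a smaller radius to keep its voxel share low).
#' @param ... forwarded to [fiber_bundle()] (tissue parameters).
#' @return A [phantom_spec()] with 6 bundles.
#' @export
evaluation_phantom_spec <- function(grid_shape = c(16, 16, 16),
                                    voxel_size = 1, radius = 3.6, ...) {
  ext <- max(grid_shape) * voxel_size
  off <- 5 * voxel_size
  dxz <- function(a) c(sin(a * pi / 180), 0, cos(a * pi / 180))
  mk <- function(u, ctr, r) {
    fiber_bundle(rbind(ctr - ext * u, ctr + ext * u), radius = r, ...)
  }
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size, bundles = list(
    mk(c(1, 0, 0), c(0, -off, 0), radius),     # site 1: 90 deg crossing
    mk(c(0, 0, 1), c(0, -off, 0), radius),
    mk(dxz(37.5), c(0, off, 0), radius),       # site 2: 75 deg crossing
    mk(dxz(-37.5), c(0, off, 0), radius),
    mk(dxz(22.5), c(0, 0, 0), 1.4),            # site 3: 45 deg crossing
    mk(dxz(-22.5), c(0, 0, 0), 1.4)))
}

#' 27-bundle spherical phantom configuration
#'
#' A deterministic stand-in for the classic 27-bundle spherical crossing
#' phantom: 27 straight chords of a sphere, with directions and offsets drawn
#' from a fixed seed, clipped so every centerline lies inside the domain.
#' Provided as a larger-scale configuration; the desk-scale tests use
#' [crossing_phantom_spec()].
#'
#' @param grid_shape voxel counts (default 32^3).
#' @param voxel_size voxel edge, mm.
#' @param seed RNG seed for the chord configuration.
#' @return A [phantom_spec()] with 27 bundles.
#' @export
spherical27_phantom_spec <- function(grid_shape = c(32, 32, 32),
                                     voxel_size = 1, seed = 27) {
  set.seed(as.integer(seed))
  R <- max(grid_shape) * voxel_size / 2
  rad <- R / 10
  bundles <- vector("list", 27)
  for (i in 1:27) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ctr <- stats::runif(3, -0.4 * R, 0.4 * R)
    # half-length so the cylinder (centerline + radius) stays inside the sphere
    half <- sqrt(max(0, (0.95 * R - rad)^2 - sum((ctr - sum(ctr * u) * u)^2)))
    half <- min(half, 0.9 * R)
    bundles[[i]] <- fiber_bundle(rbind(ctr - half * u, ctr + half * u),
                                 radius = rad)
  }
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
               domain_radius = R, bundles = bundles)
}

# voxel center coordinates of a phantom grid, mm, centered on the origin
.grid_centers <- function(spec) {
  ax <- lapply(spec$grid_shape, function(n)
    (seq_len(n) - (n + 1) / 2) * spec$voxel_size)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# distance from points (M x 3) to a polyline, plus tangent of nearest segment
.polyline_dist <- function(pts, centerline) {
  m <- nrow(pts)
  best <- rep(Inf, m)
  tang <- matrix(0, m, 3)
  for (k in seq_len(nrow(centerline) - 1)) {
    a <- centerline[k, ]; b <- centerline[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t_par <- .clamp((sweep(pts, 2, a) %*% ab) / len2, 0, 1)
    proj <- matrix(a, m, 3, byrow = TRUE) + t_par %*% t(ab) / 1
    dd <- sqrt(rowSums((pts - proj)^2))
    upd <- dd < best
    best[upd] <- dd[upd]
    tang[upd, ] <- matrix(ab / sqrt(len2), sum(upd), 3, byrow = TRUE)
  }
  list(dist = best, tangent = tang)
}

#' Rasterize a phantom specification to ground truth
#'
#' For every voxel center inside the spherical domain, tests membership in
#' each bundle cylinder (distance from center to the bundle centerline at
#' most the bundle radius). A voxel inside k bundles receives k fiber
#' directions (local centerline tangents) with equal volume fractions; if
#' k > 3 only the three largest fractions are kept (ties broken by bundle
#' order) and renormalized. The rasterization is deterministic; `seed` is
#' accepted for interface symmetry with the stochastic stages.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer, unused by the deterministic rasterizer.
#' @return An object of class `ground_truth`: arrays `directions`
#'   (nvox x 3 x 3), `fractions` (nvox x 3), `n_fibers` (nvox), logical
#'   `domain` mask (nvox), per-voxel bundle tissue parameter vectors, the
#'   originating `spec`, and `dim`/`voxel_size`. Voxel order is
#'   column-major over the grid.
#' @export
build_ground_truth <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- .grid_centers(spec)
  nvox <- nrow(pts)
  nb <- length(spec$bundles)
  inside <- matrix(FALSE, nvox, nb)
  tangents <- vector("list", nb)
  for (j in seq_len(nb)) {
    b <- spec$bundles[[j]]
    pd <- .polyline_dist(pts, b$centerline)
    inside[, j] <- pd$dist <= b$radius
    tangents[[j]] <- pd$tangent
  }
  domain <- sqrt(rowSums(pts^2)) <= spec$domain_radius
  inside[!domain, ] <- FALSE
  dirs <- array(0, c(nvox, 3, 3))
  fracs <- matrix(0, nvox, 3)
  nu <- matrix(0, nvox, 3)
  lpar <- matrix(0, nvox, 3)
  lperp <- matrix(0, nvox, 3)
  k <- rowSums(inside)
  for (v in which(k > 0)) {
    js <- which(inside[v, ])
    if (length(js) > 3) js <- js[1:3]          # equal fractions: keep first 3
    nf <- length(js)
    for (s in seq_len(nf)) {
      j <- js[s]
      dirs[v, s, ] <- tangents[[j]][v, ]
      fracs[v, s] <- 1 / nf
      nu[v, s] <- spec$bundles[[j]]$intra_fraction
      lpar[v, s] <- spec$bundles[[j]]$lambda_par
      lperp[v, s] <- spec$bundles[[j]]$lambda_perp
    }
  }
  structure(list(directions = dirs, fractions = fracs,
                 n_fibers = pmin(k, 3L), domain = domain,
                 nu = nu, lambda_par = lpar, lambda_perp = lperp,
                 spec = spec, dim = spec$grid_shape,
                 voxel_size = spec$voxel_size),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Phantom ground truth: %s grid, %d tissue voxels (%d fiber: %s)\n",
              paste(x$dim, collapse = "x"), sum(x$domain),
              sum(x$n_fibers > 0),
              paste(table(x$n_fibers[x$n_fibers > 0]), collapse = "/")))
  invisible(x)
}

#' Simulate the noise-free diffusion-weighted signal
#'
#' Two-compartment (stick + zeppelin) signal per fiber population plus an
#' isotropic remainder: for gradient direction d and fiber i with direction
#' u_i, volume fraction f_i and intra-axonal fraction nu,
#' `E/E0 = sum_i f_i * (nu * exp(-b * lpar * (d.u_i)^2)
#'          + (1-nu) * exp(-b * (lperp + (lpar-lperp) * (d.u_i)^2)))
#'          + (1 - sum_i f_i) * exp(-b * D_iso)`.
#' Background voxels (outside the spherical domain) have zero signal.
#'
#' @param gt a [build_ground_truth()] result.
#' @param scheme a [gradient_scheme()]; its `bvalue` is used unless `b` is
#'   given.
#' @param acq an [acquisition_params()] (supplies `S0` and optionally `b`).
#' @param b optional scalar b-value override, s/mm^2.
#' @return A `dwi_volume`: 4D array (x, y, z, direction) bound to `scheme`.
#' @export
simulate_signal <- function(gt, scheme, acq = acquisition_params(), b = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(scheme, "gradient_scheme"))
  bvals <- if (!is.null(b)) rep(b, nrow(scheme$directions)) else scheme$bvalue
  if (!is.null(acq$b)) bvals <- rep(acq$b, nrow(scheme$directions))
  if (any(bvals < 0)) .stopf("b must be >= 0")
  D <- scheme$directions
  n <- nrow(D)
  nvox <- prod(gt$dim)
  sig <- matrix(0, nvox, n)
  f_tot <- rowSums(gt$fractions)
  bm <- matrix(bvals, nvox, n, byrow = TRUE)
  for (s in 1:3) {
    f <- gt$fractions[, s]
    any_f <- f > 0
    if (!any(any_f)) next
    dot2 <- (gt$directions[, s, ] %*% t(D))^2
    nu <- gt$nu[, s]; lp <- gt$lambda_par[, s]; lq <- gt$lambda_perp[, s]
    stick <- exp(-bm * lp * dot2)
    zepp <- exp(-bm * (lq + (lp - lq) * dot2))
    sig <- sig + f * (nu * stick + (1 - nu) * zepp)
  }
  iso <- (1 - f_tot) * exp(-outer(rep(gt$spec$iso_diffusivity, nvox), bvals))
  sig <- sig + iso
  sig[!gt$domain, ] <- 0
  sig <- sig * acq$S0
  dwi_volume(array(sig, c(gt$dim, n)), scheme,
             voxel_size = gt$voxel_size, kind = "noise-free")
}

#' DWI volume container
#'
#' A 4D diffusion-weighted signal array (x, y, z, direction) bound to the
#' [gradient_scheme()] that produced its 4th dimension.
#'
#' @param data 4D numeric array.
#' @param scheme a [gradient_scheme()]; `dim(data)[4]` must equal the number
#'   of directions (plus any b0 volumes indexed by `b0_idx`).
#' @param voxel_size voxel edge, mm.
#' @param kind free-text provenance tag ("noise-free", "noisy", "denoised").
#' @param b0_idx integer indices of unweighted volumes along dim 4.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, voxel_size = 1, kind = "raw",
                       b0_idx = integer(0)) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  data <- as.array(data)
  if (length(dim(data)) != 4L) .stopf("data must be a 4D array")
  if (dim(data)[4] != nrow(scheme$directions) + length(b0_idx))
    .stopf("4th dimension (%d) must match scheme directions (%d) + b0 (%d)",
           dim(data)[4], nrow(scheme$directions), length(b0_idx))
  structure(list(data = data, scheme = scheme, voxel_size = voxel_size,
                 kind = kind, b0_idx = as.integer(b0_idx)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat(sprintf("DWI volume (%s): %s, %d directions, %d b0\n", x$kind,
              paste(dim(x$data)[1:3], collapse = "x"),
              nrow(x$scheme$directions), length(x$b0_idx)))
  invisible(x)
}

#' Add Rician noise at a prescribed SNR
#'
#' Magnitude-MR noise: each sample s is replaced by
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma^2)` independent
#' across voxels and directions, `sigma = S0 / snr`. SNR is defined against
#' the unweighted signal S0. `snr = Inf` returns the input unchanged.
#'
#' @param vol a [dwi_volume()] (or plain numeric array).
#' @param snr target signal-to-noise ratio, > 0.
#' @param seed integer RNG seed for reproducibility.
#' @param S0 unweighted signal level defining sigma.
#' @return Object of the same type as `vol` with noisy values (kind "noisy").
#' @export
add_rician_noise <- function(vol, snr, seed, S0 = 1.0) {
  if (!is.numeric(snr) || snr <= 0) .stopf("snr must be > 0")
  x <- if (inherits(vol, "dwi_volume")) vol$data else vol
  if (is.infinite(snr)) return(vol)
  if (!missing(seed)) set.seed(as.integer(seed))
  sigma <- S0 / snr
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  y <- sqrt((x + n1)^2 + n2^2)
  if (inherits(vol, "dwi_volume")) {
    vol$data <- array(y, dim(x))
    vol$kind <- "noisy"
    vol
  } else array(y, dim(x) %||% length(x))
}
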