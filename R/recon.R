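#' Real symmetric spherical harmonic design matrix
#'
#' Builds the modified real, even-degree spherical harmonic basis commonly
#' used for antipodally symmetric spherical signals: for degree l (even) and
#' order m, the basis function is `sqrt(2) * N_lm * P_l^|m|(cos theta) *
#' sin(|m| phi)` for m < 0, `N_l0 * P_l(cos theta)` for m = 0 and
#' `sqrt(2) * N_lm * P_l^m(cos theta) * cos(m phi)` for m > 0, with the
#' orthonormalization constant `N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!)`.
#' Spherical convention: `theta = acos(z)` (polar), `phi = atan2(y, x)`
#' (azimuth). The basis has `R = (order+1)(order+2)/2` functions (45 for
#' order 8) and is orthonormal on the sphere. The Laplace-Beltrami penalty
#' diagonal `l^2 (l+1)^2` per coefficient is returned alongside.
#'
#' @param order maximum (even) SH degree.
#' @param directions N x 3 matrix of unit vectors (or a [gradient_scheme()]).
#' @return An object of class `sh_basis`: list with `B` (N x R design
#'   matrix), `lb_diag` (length R), `l_degree`, `m_order`, `order`.
#' @export
sh_design_matrix <- function(order, directions) {
  if (order %% 2 != 0 || order < 0) .stopf("order must be even and >= 0")
  if (inherits(directions, "gradient_scheme"))
    directions <- directions$directions
  directions <- as.matrix(directions)
  if (nrow(directions) < 1) .stopf("directions must be nonempty")
  theta <- acos(.clamp(directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  x <- cos(theta)
  ls <- seq(0, order, by = 2)
  R <- (order + 1) * (order + 2) / 2
  B <- matrix(0, nrow(directions), R)
  l_degree <- integer(R)
  m_order <- integer(R)
  j <- 0
  for (l in ls) {
    # pracma::legendre returns (l+1) x N matrix of P_l^m, m = 0..l,
    # MATLAB convention (Condon-Shortley phase included)
    P <- if (l == 0) matrix(1, 1, length(x)) else pracma::legendre(l, x)
    for (m in -l:l) {
      j <- j + 1
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[am + 1, ]
      B[, j] <- if (m < 0) sqrt(2) * nlm * plm * sin(am * phi)
        else if (m == 0) nlm * plm
        else sqrt(2) * nlm * plm * cos(m * phi)
      l_degree[j] <- l
      m_order[j] <- m
    }
  }
  structure(list(B = B, lb_diag = l_degree^2 * (l_degree + 1)^2,
                 l_degree = l_degree, m_order = m_order, order = order),
            class = "sh_basis")
}

#' @export
print.sh_basis <- function(x, ...) {
  cat(sprintf("SH basis: order %d, %d functions, %d directions\n",
              x$order, ncol(x$B), nrow(x$B)))
  invisible(x)
}

#' Laplace-Beltrami regularized spherical harmonic fit
#'
#' Solves `c = (B'B + lambda L)^-1 B' s` where L is the diagonal
#' Laplace-Beltrami penalty `l^2 (l+1)^2`. With lambda = 0 this is ordinary
#' least squares and requires at least as many directions as coefficients.
#'
#' @param s numeric vector of length N, or an N x V matrix (one column per
#'   voxel) for a vectorized fit.
#' @param basis an [sh_design_matrix()] result.
#' @param lambda_reg regularization constant (dimensionless; 0.006 is the
#'   standard choice for order-8 Q-ball).
#' @return Coefficient vector of length R (or R x V matrix).
#' @export
fit_sh_regularized <- function(s, basis, lambda_reg = 0.006) {
  stopifnot(inherits(basis, "sh_basis"))
  B <- basis$B
  s <- as.matrix(s)
  if (nrow(s) != nrow(B)) .stopf("signal length %d != %d directions",
                                 nrow(s), nrow(B))
  A <- crossprod(B) + lambda_reg * diag(basis$lb_diag)
  if (lambda_reg == 0 && nrow(B) < ncol(B))
    .stopf("ill-posed: %d directions < %d coefficients and lambda = 0",
           nrow(B), ncol(B))
  cf <- tryCatch(solve(A, crossprod(B, s)),
                 error = function(e) .stopf("ill-posed SH system: %s",
                                            conditionMessage(e)))
  if (ncol(cf) == 1) drop(cf) else cf
}

# Legendre polynomial at 0: P_l(0) = (-1)^(l/2) (l-1)!! / l!!, even l
.legendre_p0 <- function(l) {
  vapply(l, function(li) {
    if (li == 0) return(1)
    k <- li / 2
    (-1)^k * exp(lgamma(li + 1) - 2 * k * log(2) - 2 * lgamma(k + 1))
  }, numeric(1))
}

#' Analytic Funk-Radon transform of SH coefficients
#'
#' Maps signal SH coefficients to diffusion ODF coefficients:
#' `c'_lm = 2 pi P_l(0) c_lm`, the analytic form of the great-circle
#' integral transform in the SH basis.
#'
#' @param coef coefficient vector (length R) or R x V matrix.
#' @param basis the [sh_design_matrix()] the coefficients live in.
#' @return Transformed coefficients, same shape.
#' @export
qball_frt <- function(coef, basis) {
  stopifnot(inherits(basis, "sh_basis"))
  scale <- 2 * pi * .legendre_p0(basis$l_degree)
  if (is.matrix(coef)) coef * scale else drop(coef * scale)
}

#' Subdivided icosahedron sphere tessellation
#'
#' Repeatedly subdivides the faces of a regular icosahedron and projects the
#' vertices to the unit sphere: 12, 42, 162, 642 vertices at 0..3
#' subdivisions. The tessellation is antipodally symmetric and the triangle
#' edges define the neighborhood graph used for local-maximum detection.
#'
#' @param subdivisions number of 4-fold face subdivisions (default 3).
#' @return A list with `vertices` (V x 3 unit rows), `faces` (F x 3 vertex
#'   indices) and `neighbors` (list of vertex index vectors).
#' @export
icosphere <- function(subdivisions = 3) {
  t0 <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t0, 0), c(1, t0, 0), c(-1, -t0, 0), c(1, -t0, 0),
             c(0, -1, t0), c(0, 1, t0), c(0, -1, -t0), c(0, 1, -t0),
             c(t0, 0, -1), c(t0, 0, 1), c(-t0, 0, -1), c(-t0, 0, 1))
  v <- .unit_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "-")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  edges <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                        f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
  nbrs <- split(edges[, 2], edges[, 1])
  neighbors <- lapply(seq_len(nrow(v)), function(i)
    sort(unique(nbrs[[as.character(i)]])))
  list(vertices = v, faces = f, neighbors = neighbors)
}

#' Extract fiber peaks from ODF spherical harmonic coefficients
#'
#' Evaluates the ODF on an antipodally symmetric sphere tessellation, finds
#' strict local maxima over the triangle neighborhood graph, min-max
#' normalizes the ODF, discards maxima whose normalized amplitude is below
#' `relative_threshold`, then selects peaks greedily by amplitude enforcing a
#' minimum symmetrized angular separation, up to `max_peaks`. Peak
#' directions are reported as canonical upper-hemisphere axes; the antipodal
#' twin of each maximum is merged by the separation rule. A constant ODF has
#' no strict local maxima and yields zero peaks.
#'
#' @param coef ODF SH coefficients: vector (one voxel) or R x V matrix.
#' @param basis the [sh_design_matrix()] used for the coefficients (only
#'   `order` is used; the tessellation design matrix is rebuilt internally).
#' @param sphere an [icosphere()] (>= 642 vertices recommended).
#' @param relative_threshold minimum normalized amplitude, default 0.1.
#' @param min_separation minimum peak separation in degrees, default 25.
#' @param max_peaks maximum peaks per voxel, default 3.
#' @return For a single voxel, a list with `directions` (k x 3) and
#'   `amplitudes`; for a matrix input, a list of class `peak_set` with
#'   per-voxel `peaks` (list of k x 3 matrices), `amplitudes` and `counts`.
#' @export
extract_peaks <- function(coef, basis, sphere = icosphere(3),
                          relative_threshold = 0.1, min_separation = 25,
                          max_peaks = 3) {
  stopifnot(inherits(basis, "sh_basis"))
  single <- !is.matrix(coef)
  cf <- if (single) matrix(coef, ncol = 1) else coef
  Bs <- sh_design_matrix(basis$order, sphere$vertices)$B
  vals <- Bs %*% cf                        # V x nvox ODF values
  nbr <- sphere$neighbors
  nvert <- nrow(sphere$vertices)
  # strict local maxima: value greater than every neighbor
  nbr_max <- matrix(-Inf, nvert, ncol(vals))
  for (i in seq_len(nvert)) {
    nb <- nbr[[i]]
    nbr_max[i, ] <- do.call(pmax, lapply(nb, function(j) vals[j, ]))
  }
  is_max <- vals > nbr_max
  out <- vector("list", ncol(vals))
  amps <- vector("list", ncol(vals))
  for (vx in seq_len(ncol(vals))) {
    vv <- vals[, vx]
    rng <- range(vv)
    if (rng[2] - rng[1] < 1e-12) {
      out[[vx]] <- matrix(0, 0, 3); amps[[vx]] <- numeric(0); next
    }
    norm <- (vv - rng[1]) / (rng[2] - rng[1])
    cand <- which(is_max[, vx] & norm >= relative_threshold)
    cand <- cand[order(vv[cand], decreasing = TRUE)]
    sel <- integer(0)
    for (ci in cand) {
      if (length(sel) >= max_peaks) break
      ok <- all(vapply(sel, function(sj)
        .axis_angle_deg(sphere$vertices[ci, ], sphere$vertices[sj, ]) >=
          min_separation, logical(1)))
      if (ok) sel <- c(sel, ci)
    }
    dirs <- sphere$vertices[sel, , drop = FALSE]
    if (nrow(dirs)) dirs <- t(apply(dirs, 1, .canonical_axis))
    out[[vx]] <- dirs
    amps[[vx]] <- vv[sel]
  }
  if (single) return(list(directions = out[[1]], amplitudes = amps[[1]]))
  structure(list(peaks = out, amplitudes = amps,
                 counts = vapply(out, nrow, integer(1))),
            class = "peak_set")
}

#' Q-ball peak extraction pipeline for a DWI volume
#'
#' Convenience wrapper: regularized SH fit of the normalized signal in every
#' (masked) voxel, analytic Funk-Radon transform, peak extraction.
#'
#' @param vol a [dwi_volume()] (weighted volumes only) or 4D array.
#' @param scheme the [gradient_scheme()] (taken from `vol` if absent).
#' @param mask logical 3D array of voxels to reconstruct (default: all).
#' @param order SH order (default 8).
#' @param lambda_reg regularization constant (default 0.006).
#' @param sphere an [icosphere()].
#' @param ... forwarded to [extract_peaks()].
#' @return A `peak_set` over the masked voxels, with attribute `voxels`
#'   giving their linear indices.
#' @export
qball_peaks <- function(vol, scheme = NULL, mask = NULL, order = 8,
                        lambda_reg = 0.006, sphere = icosphere(3), ...) {
  if (inherits(vol, "dwi_volume")) {
    scheme <- scheme %||% vol$scheme
    x <- vol$data
  } else x <- as.array(vol)
  stopifnot(inherits(scheme, "gradient_scheme"))
  dims <- dim(x)
  nvox <- prod(dims[1:3])
  m <- matrix(x, nvox, dims[4])
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  basis <- sh_design_matrix(order, scheme$directions)
  cf <- fit_sh_regularized(t(m[vox, , drop = FALSE]), basis, lambda_reg)
  if (!is.matrix(cf)) cf <- matrix(cf, ncol = 1)
  odf <- qball_frt(cf, basis)
  ps <- extract_peaks(odf, basis, sphere = sphere, ...)
  attr(ps, "voxels") <- vox
  ps
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least-squares fit of `log S = log S0 - b g' D g` per voxel, with
#' the 6 unique tensor elements and log S0 as unknowns. Nonpositive signals
#' are clamped to a small epsilon (reported via `message()`). Fractional
#' anisotropy is computed from the eigenvalues by the standard
#' normalized-variance formula and eigenvectors are sorted by descending
#' eigenvalue.
#'
#' @param vol a [dwi_volume()] or 4D array (may include b0 frames indexed by
#'   the volume's `b0_idx`).
#' @param scheme the [gradient_scheme()] (taken from `vol` if absent).
#' @param mask optional logical 3D array.
#' @return An object of class `dti_fit`: `tensors` (nvox x 6:
#'   Dxx,Dyy,Dzz,Dxy,Dxz,Dyz), `fa`, `md`, `v1` (nvox x 3 principal
#'   eigenvector), `eigenvalues` (nvox x 3), `voxels` (linear indices),
#'   `dim`.
#' @export
fit_dti <- function(vol, scheme = NULL, mask = NULL) {
  if (inherits(vol, "dwi_volume")) {
    scheme <- scheme %||% vol$scheme
    x <- vol$data
    b0_idx <- vol$b0_idx
  } else {
    x <- as.array(vol); b0_idx <- integer(0)
  }
  stopifnot(inherits(scheme, "gradient_scheme"))
  dims <- dim(x)
  nvox <- prod(dims[1:3])
  m <- matrix(x, nvox, dims[4])
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  dwi_idx <- setdiff(seq_len(dims[4]), b0_idx)
  g <- scheme$directions
  b <- scheme$bvalue
  if (nrow(g) < 6) .stopf("need >= 6 gradient directions")
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  cols <- c(dwi_idx, b0_idx)
  Xfull <- rbind(X, matrix(rep(c(1, rep(0, 6)), length(b0_idx)),
                           ncol = 7, byrow = TRUE))
  S <- t(m[vox, cols, drop = FALSE])
  n_bad <- sum(S <= 0)
  if (n_bad > 0) {
    message(sprintf("fit_dti: clamped %d nonpositive signals", n_bad))
    S[S <= 0] <- 1e-8
  }
  beta <- qr.solve(Xfull, log(S))          # 7 x V
  nv <- length(vox)
  fa <- md <- numeric(nv)
  evs <- matrix(0, nv, 3)
  v1 <- matrix(0, nv, 3)
  for (i in seq_len(nv)) {
    d <- beta[2:7, i]
    Dm <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)
    ev <- e$values
    evs[i, ] <- ev
    v1[i, ] <- e$vectors[, 1]
    md[i] <- mean(ev)
    denom <- sum(ev^2)
    fa[i] <- if (denom <= 0) 0 else
      sqrt(1.5 * sum((ev - mean(ev))^2) / denom)
  }
  structure(list(tensors = t(beta[2:7, , drop = FALSE]), fa = fa, md = md,
                 v1 = v1, eigenvalues = evs, voxels = vox, dim = dims[1:3]),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("DTI fit: %d voxels, mean FA %.3f, mean MD %.2e mm^2/s\n",
              length(x$voxels), mean(x$fa), mean(x$md)))
  invisible(x)
}
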