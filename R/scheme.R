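#' Gradient scheme objects
#'
#' A `gradient_scheme` holds an ordered set of unit diffusion-gradient
#' directions together with their b-values and the acquisition position of
#' each direction along the sampling curve. Directions are axes: the
#' diffusion-weighted signal is antipodally symmetric, `E(b, d) = E(b, -d)`,
#' so a direction and its antipode are the same measurement.
#'
#' @param directions numeric matrix, N x 3, unit rows.
#' @param bvalue diffusion weighting in s/mm^2; scalar (recycled) or length N.
#' @param order_index integer vector, a permutation of `0:(N-1)` giving the
#'   acquisition position of each row along the sampling curve (0-based).
#' @param kind one of `"exact_spiral"`, `"uneven_spiral"`, `"electrostatic"`.
#' @param n_b0 count of unweighted (b0) volumes associated with the scheme.
#' @return An object of class `gradient_scheme`: a list with elements
#'   `directions`, `bvalue`, `order_index`, `kind`, `n_b0`.
#' @export
gradient_scheme <- function(directions, bvalue = 0, order_index = NULL,
                            kind = c("exact_spiral", "uneven_spiral",
                                     "electrostatic"),
                            n_b0 = 0L) {
  kind <- match.arg(kind)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) .stopf("directions must be an N x 3 matrix")
  n <- nrow(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-12)) directions <- directions / nrm
  if (length(bvalue) == 1L) bvalue <- rep(bvalue, n)
  if (length(bvalue) != n) .stopf("bvalue must be scalar or length N")
  if (is.null(order_index)) order_index <- seq_len(n) - 1L
  order_index <- as.integer(order_index)
  if (!identical(sort(order_index), seq_len(n) - 1L))
    .stopf("order_index must be a permutation of 0..N-1")
  structure(list(directions = directions, bvalue = as.numeric(bvalue),
                 order_index = order_index, kind = kind,
                 n_b0 = as.integer(n_b0)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme (%s): %d directions, %d b0, b = %s s/mm^2\n",
              x$kind, nrow(x$directions), x$n_b0,
              paste(unique(round(x$bvalue, 1)), collapse = "/")))
  invisible(x)
}

# arc length of the spherical spiral phi = c * theta from 0 to theta
.spiral_arclen <- function(theta, c_rate) {
  vapply(theta, function(th) {
    if (th <= 0) return(0)
    stats::integrate(function(t) sqrt(1 + c_rate^2 * sin(t)^2), 0, th,
                     rel.tol = 1e-12, subdivisions = 400L)$value
  }, numeric(1))
}

# invert s(theta) = target on [0, upper] by bisection/uniroot
.spiral_invert <- function(targets, c_rate, upper) {
  vapply(targets, function(s0) {
    if (s0 <= 0) return(0)
    stats::uniroot(function(th) .spiral_arclen(th, c_rate) - s0,
                   lower = 0, upper = upper, tol = 1e-13)$root
  }, numeric(1))
}

#' Analytically exact uniform spherical spiral scheme
#'
#' Places `n_total` unit vectors at equal arc-length intervals along the
#' spherical spiral `theta in [0, pi]`, `phi = c * theta` with `c = 2 * turns`.
#' The set is antipodally symmetric by construction: `n_total/2` points are
#' spaced at equal arc length along the spiral from the north pole to the
#' equator and their exact antipodes are appended in reverse spiral order, so
#' the first point is the north pole, the last is the south pole, and
#' [to_hemisphere()] collapses the scheme to `n_total/2` directions forming a
#' contiguous spiral on the upper hemisphere.
#'
#' Arc length `s(theta) = integral of sqrt(1 + c^2 sin^2 t) dt` is computed by
#' adaptive quadrature and inverted by root finding. With `turns = "auto"` the
#' number of turns is `round(sqrt(n_total * pi) / 2)`, which equates spacing
#' along the spiral with the spacing between adjacent turns, giving a nearly
#' uniform spherical point density.
#'
#' @param n_total even integer >= 4, number of points on the full sphere.
#' @param turns positive number of spiral turns over `theta in [0, pi]`, or
#'   `"auto"`.
#' @param bvalue b-value attached to the scheme (s/mm^2).
#' @return A [gradient_scheme()] of kind `"exact_spiral"`.
#' @export
generate_exact_spiral <- function(n_total, turns = "auto", bvalue = 0) {
  if (!is.numeric(n_total) || n_total < 4) .stopf("n_total must be >= 4")
  n_total <- as.integer(n_total)
  if (n_total %% 2L != 0L)
    .stopf("n_total must be even (antipodally symmetric construction)")
  if (identical(turns, "auto")) turns <- round(sqrt(n_total * pi) / 2)
  if (!is.numeric(turns) || turns <= 0) .stopf("turns must be positive")
  c_rate <- 2 * turns
  m <- n_total %/% 2L
  s_half <- .spiral_arclen(pi / 2, c_rate)
  targets <- seq(0, s_half, length.out = m)
  theta <- .spiral_invert(targets, c_rate, upper = pi / 2 + 1e-9)
  theta[m] <- pi / 2
  phi <- c_rate * theta
  upper <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  pts <- rbind(upper, -upper[m:1, , drop = FALSE])
  gradient_scheme(pts, bvalue = bvalue, kind = "exact_spiral")
}

#' Reduce a scheme to the hemisphere
#'
#' Replaces every direction with its canonical hemisphere representative
#' (z > 0; ties at z = 0 broken by x > 0 then y > 0 -- valid because the DWI
#' signal is antipodally symmetric) and collapses directions that become
#' duplicates, keeping the copy with the earlier acquisition position.
#' `order_index` is re-packed contiguously preserving the original relative
#' acquisition order.
#'
#' @param scheme a [gradient_scheme()].
#' @param tol angular tolerance (radians on chord) for duplicate collapse.
#' @return A [gradient_scheme()] with all directions on the upper hemisphere.
#' @export
to_hemisphere <- function(scheme, tol = 1e-8) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- scheme$directions
  canon <- t(apply(d, 1, .canonical_axis))
  acq <- order(scheme$order_index)      # rows in acquisition order
  keep <- logical(nrow(d))
  kept_rows <- NULL
  for (i in acq) {
    if (is.null(kept_rows)) dup <- FALSE
    else dup <- any(sqrt(rowSums((kept_rows - matrix(canon[i, ], nrow(kept_rows),
                                                     3, byrow = TRUE))^2)) < tol)
    if (!dup) {
      keep[i] <- TRUE
      kept_rows <- rbind(kept_rows, canon[i, ])
    }
  }
  idx <- which(keep)
  idx <- idx[order(scheme$order_index[idx])]
  gradient_scheme(canon[idx, , drop = FALSE],
                  bvalue = scheme$bvalue[idx],
                  order_index = seq_along(idx) - 1L,
                  kind = scheme$kind, n_b0 = scheme$n_b0)
}

#' Uneven periodic spiral scheme
#'
#' Hemisphere spiral with a fixed azimuthal angular step: point `k`
#' (`k = 0..n-1`) has azimuth `phi_k = k * azimuth_step (mod 360)` and polar
#' angle `theta_k = k * 90 / (n - 1)` degrees, sweeping linearly in theta from
#' the pole to the equator. Sampling density is uneven (dense near the pole),
#' which is the scheme's defining property.
#'
#' @param n number of directions, >= 2.
#' @param azimuth_step azimuthal step in degrees, in (0, 360).
#' @param bvalue b-value (s/mm^2).
#' @return A [gradient_scheme()] of kind `"uneven_spiral"`.
#' @export
generate_uneven_spiral <- function(n, azimuth_step = 20, bvalue = 0) {
  if (!is.numeric(n) || n < 2) .stopf("n must be >= 2")
  if (!is.numeric(azimuth_step) || azimuth_step <= 0 || azimuth_step >= 360)
    .stopf("azimuth_step must be in (0, 360) degrees")
  n <- as.integer(n)
  k <- seq_len(n) - 1
  theta <- k * (pi / 2) / (n - 1)
  phi <- k * azimuth_step * pi / 180
  pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  gradient_scheme(pts, bvalue = bvalue, kind = "uneven_spiral")
}

# symmetrized Coulomb energy of a hemisphere point set (points + antipodes)
.electro_energy <- function(p) {
  q <- rbind(p, -p)
  dm <- as.matrix(stats::dist(q))
  sum(1 / dm[upper.tri(dm)])
}

#' Electrostatic repulsion scheme
#'
#' Distributes `n` directions on the hemisphere by minimizing the antipodally
#' symmetrized Coulomb energy `sum 1/||p_i - p_j||` over the 2n-point set of
#' directions and their antipodes. Starting from a seeded random
#' configuration, pairwise inverse-square repulsive forces are projected onto
#' the sphere tangent plane and applied with a decaying step size, with
#' renormalization after every step; a step that raises the energy is
#' rejected and the step size halved. Deterministic given `seed`.
#'
#' @param n number of directions, >= 2.
#' @param seed integer RNG seed (mandatory: the optimum is degenerate under
#'   rotation, the seed fixes the representative).
#' @param iterations number of repulsion steps.
#' @param bvalue b-value (s/mm^2).
#' @return A [gradient_scheme()] of kind `"electrostatic"`.
#' @export
generate_electrostatic <- function(n, seed, iterations = 1000, bvalue = 0) {
  if (!is.numeric(n) || n < 2) .stopf("n must be >= 2")
  if (missing(seed)) .stopf("seed is required")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  p <- .unit_rows(matrix(stats::rnorm(3 * n), n, 3))
  energy <- .electro_energy(p)
  step <- 0.1
  for (it in seq_len(iterations)) {
    q <- rbind(p, -p)
    frc <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      dv <- matrix(p[i, ], 2 * n, 3, byrow = TRUE) - q
      r2 <- rowSums(dv^2)
      ok <- r2 > 1e-12
      f <- colSums(dv[ok, , drop = FALSE] / r2[ok]^1.5)
      frc[i, ] <- f - sum(f * p[i, ]) * p[i, ]   # tangential component
    }
    fmax <- max(sqrt(rowSums(frc^2)))
    if (fmax < 1e-12) break
    cand <- .unit_rows(p + step / fmax * frc)
    e2 <- .electro_energy(cand)
    if (e2 < energy) {
      p <- cand; energy <- e2; step <- min(step * 1.05, 0.2)
    } else {
      step <- step / 2
      if (step < 1e-9) break
    }
  }
  p <- t(apply(p, 1, .canonical_axis))
  gradient_scheme(p, bvalue = bvalue, kind = "electrostatic")
}

#' Uniformity metrics of a gradient scheme
#'
#' Quantifies how evenly a scheme samples orientation space. Because
#' directions are axes, all metrics are antipodally symmetrized:
#' `min_pairwise_angle` is the smallest `acos(|d_i . d_j|)` over distinct
#' axes (antipodal duplicates collapsed first), `electrostatic_energy` is
#' `sum 1/||p_i - p_j||` over the collapsed axes and their antipodes, and
#' `max_consecutive_step` is the largest symmetrized angle between
#' consecutive directions along the acquisition order.
#'
#' @param scheme a [gradient_scheme()] with >= 2 directions.
#' @return A list of class `uniformity_report` with `min_pairwise_angle`,
#'   `electrostatic_energy`, `max_consecutive_step` (degrees / dimensionless).
#' @export
uniformity_metrics <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- scheme$directions
  if (nrow(d) < 2) .stopf("need >= 2 directions")
  acq <- d[order(scheme$order_index), , drop = FALSE]
  steps <- vapply(seq_len(nrow(acq) - 1),
                  function(i) .axis_angle_deg(acq[i, ], acq[i + 1, ]),
                  numeric(1))
  hemi <- to_hemisphere(scheme)
  h <- hemi$directions
  g <- abs(.clamp(tcrossprod(h)))
  diag(g) <- 0
  min_ang <- 180 / pi * acos(max(g))
  structure(list(min_pairwise_angle = min_ang,
                 electrostatic_energy = .electro_energy(h),
                 max_consecutive_step = max(steps)),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf(paste0("Uniformity: min pairwise angle %.2f deg, ",
                     "energy %.2f, max consecutive step %.2f deg\n"),
              x$min_pairwise_angle, x$electrostatic_energy,
              x$max_consecutive_step))
  invisible(x)
}

#' Write / read a gradient scheme as text
#'
#' The scheme text format has one direction per line, `x y z b`, `#` comment
#' lines allowed; line order is acquisition order. `write_fsl_gradients()`
#' and `read_fsl_gradients()` handle FSL-dialect `bvec` (3 rows x N, one row
#' per component; an N x 3 column layout is also accepted on read) and `bval`
#' (single row) files.
#'
#' @param scheme a [gradient_scheme()].
#' @param path output file path (for FSL writers, a prefix: `<prefix>.bvec`,
#'   `<prefix>.bval`).
#' @param kind scheme kind to assign on read.
#' @return `read_scheme()` and `read_fsl_gradients()` return a
#'   [gradient_scheme()]; writers return the path invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- scheme$directions[order(scheme$order_index), , drop = FALSE]
  b <- scheme$bvalue[order(scheme$order_index)]
  lines <- c(sprintf("# gradient scheme: kind=%s n=%d n_b0=%d",
                     scheme$kind, nrow(d), scheme$n_b0),
             sprintf("%.16g %.16g %.16g %.10g", d[, 1], d[, 2], d[, 3], b))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path, kind = "exact_spiral") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) && grepl("kind=", hdr[1]))
    kind <- sub(".*kind=([a-z_]+).*", "\\1", hdr[1])
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 4L) .stopf("scheme file must have 4 columns: x y z b")
  gradient_scheme(m[, 1:3, drop = FALSE], bvalue = m[, 4], kind = kind)
}

#' @rdname write_scheme
#' @export
write_fsl_gradients <- function(scheme, path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- scheme$directions[order(scheme$order_index), , drop = FALSE]
  b <- scheme$bvalue[order(scheme$order_index)]
  rows <- apply(t(d), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, sprintf("%s.bvec", path))
  writeLines(paste(sprintf("%.10g", b), collapse = " "),
             sprintf("%s.bval", path))
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_fsl_gradients <- function(path, kind = "exact_spiral") {
  bvec <- as.matrix(utils::read.table(sprintf("%s.bvec", path)))
  bval <- as.numeric(utils::read.table(sprintf("%s.bval", path)))
  dirs <- .parse_bvec(bvec)
  if (nrow(dirs) != length(bval)) .stopf("bvec/bval length mismatch")
  nz <- sqrt(rowSums(dirs^2)) > 0
  dirs[nz, ] <- .unit_rows(dirs[nz, , drop = FALSE])
  gradient_scheme(dirs[nz, , drop = FALSE], bvalue = bval[nz], kind = kind,
                  n_b0 = sum(!nz))
}

# accept 3 x N (FSL) or N x 3 bvec layouts; ambiguous 3 x 3 read as FSL rows
.parse_bvec <- function(bvec) {
  bvec <- unname(as.matrix(bvec))
  if (nrow(bvec) == 3L) t(bvec)
  else if (ncol(bvec) == 3L) bvec
  else .stopf("bvec must be 3 x N or N x 3")
}
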