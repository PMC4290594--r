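# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# cumulative arc length of the spiral phi = c * theta by dense trapezoid rule
oracle_arclen <- function(theta, c_rate, n_grid = 200000) {
  tg <- seq(0, max(theta), length.out = n_grid)
  f <- sqrt(1 + c_rate^2 * sin(tg)^2)
  cum <- c(0, cumsum((f[-1] + f[-n_grid]) / 2 * diff(tg)))
  stats::approx(tg, cum, xout = theta)$y
}

# O(N^2) pairwise symmetrized angle metrics
oracle_uniformity <- function(dirs) {
  n <- nrow(dirs)
  min_ang <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- 180 / pi * acos(min(1, abs(sum(dirs[i, ] * dirs[j, ]))))
    if (a < min_ang) min_ang <- a
  }
  q <- rbind(dirs, -dirs)
  e <- 0
  for (i in seq_len(2 * n - 1)) for (j in (i + 1):(2 * n)) {
    e <- e + 1 / sqrt(sum((q[i, ] - q[j, ])^2))
  }
  list(min_pairwise_angle = min_ang, electrostatic_energy = e)
}

# direct O(N^2) DFT low-pass (retain |k| <= cutoff-1)
oracle_lowpass <- function(s, cutoff) {
  n <- length(s)
  ks <- 0:(n - 1)
  fr <- pmin(ks, n - ks)
  out <- numeric(n)
  for (m in ks) {
    acc <- 0
    for (k in ks[fr <= cutoff - 1]) {
      coef <- sum(s * exp(-2i * pi * k * ks / n))
      acc <- acc + coef * exp(2i * pi * k * m / n)
    }
    out[m + 1] <- Re(acc) / n
  }
  out
}

# exhaustive-scan Otsu: maximize between-class variance over bin edges
oracle_otsu <- function(x, n_bins = 256) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  best <- -Inf
  best_thr <- br[2]
  for (t in 2:n_bins) {
    thr <- br[t]
    lo <- x[x <= thr]
    hi <- x[x > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_thr <- thr }
  }
  best_thr
}

# numerical Funk-Radon transform: great-circle quadrature of an SH field
oracle_frt <- function(coef, basis_order, u, n_quad = 720) {
  # orthonormal frame perpendicular to u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  phi <- seq(0, 2 * pi, length.out = n_quad + 1)[-(n_quad + 1)]
  circ <- outer(cos(phi), e1) + outer(sin(phi), e2)
  B <- lopdwi::sh_design_matrix(basis_order, circ)$B
  sum(B %*% coef) * 2 * pi / n_quad
}

# textbook paired t-test
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  list(t = t, p = p)
}

# brute-force point-in-cylinder test for straight bundles
oracle_in_cylinder <- function(pts, p0, p1, radius) {
  u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  len <- sqrt(sum((p1 - p0)^2))
  apply(pts, 1, function(p) {
    t <- sum((p - p0) * u)
    t <- min(max(t, 0), len)
    q <- p0 + t * u
    sqrt(sum((p - q)^2)) <= radius
  })
}

# shared fixtures
spiral82 <- function() lopdwi::to_hemisphere(lopdwi::generate_exact_spiral(164))

# small synthetic acquisition with b0 frames, for i/o and concatenation tests
make_dataset <- function(n_dwi = 82, n_b0 = 6, dims = c(4, 4, 3), seed = 1) {
  scheme <- spiral82()
  scheme$directions <- scheme$directions[seq_len(n_dwi), , drop = FALSE]
  scheme$bvalue <- rep(3000, n_dwi)
  scheme$order_index <- seq_len(n_dwi) - 1L
  scheme$n_b0 <- as.integer(n_b0)
  set.seed(seed)
  dat <- array(abs(rnorm(prod(dims) * (n_dwi + n_b0), 0.5, 0.2)),
               c(dims, n_dwi + n_b0))
  structure(list(data = dat, scheme = scheme,
                 b0_idx = seq_len(n_b0), bvals = c(rep(0, n_b0),
                                                   rep(3000, n_dwi)),
                 affine = diag(4), voxel_size = c(2.5, 2.5, 2.5)),
            class = "dwi_dataset")
}

two_compartment_signal <- function(D, u, b, nu = 0.4, lp = 1.7e-3,
                                   lq = 0.3e-3) {
  d2 <- (D %*% u)^2
  drop(nu * exp(-b * lp * d2) + (1 - nu) * exp(-b * (lq + (lp - lq) * d2)))
}
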