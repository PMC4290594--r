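test_that("SH basis has the right shape and normalization", {
  d <- spiral82()$directions
  b0 <- sh_design_matrix(0, d)
  expect_equal(ncol(b0$B), 1)
  expect_equal(b0$B[, 1], rep(1 / sqrt(4 * pi), 82), tolerance = 1e-12)
  b8 <- sh_design_matrix(8, d)
  expect_equal(ncol(b8$B), 45)
  expect_identical(b8$lb_diag[1], 0)
  expect_error(sh_design_matrix(3, d), "even")
})

test_that("SH basis columns are orthonormal under dense spherical quadrature", {
  # uniform-ish quadrature grid: equal-area latitude bands
  n <- 10000
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  grid <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  B <- sh_design_matrix(8, grid)$B
  G <- crossprod(B) * (4 * pi / n)
  expect_lt(max(abs(G - diag(45))), 1e-3)
})

test_that("regularized SH fit recovers exact coefficients and has sensible limits", {
  set.seed(10)
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  coef_true <- rnorm(45, 0, 0.2)
  s <- drop(basis$B %*% coef_true)
  expect_equal(fit_sh_regularized(s, basis, 0), coef_true, tolerance = 1e-8)
  # huge regularization kills l > 0, keeps l = 0 near the mean
  c_inf <- fit_sh_regularized(s, basis, 1e6)
  expect_lt(max(abs(c_inf[-1])), 1e-3 * max(abs(coef_true)))
  expect_equal(c_inf[1] * 1 / sqrt(4 * pi), mean(s), tolerance = 1e-3)
  # ill-posed: fewer directions than coefficients without regularization
  b_small <- sh_design_matrix(8, d[1:20, ])
  expect_error(fit_sh_regularized(s[1:20], b_small, 0), "ill-posed")
})

test_that("regularization helps generalization on noisy single-tensor signals", {
  # fit all 82 noisy directions, evaluate on held-out directions (a dense
  # icosphere grid the fit never saw), regularized vs unregularized
  set.seed(11)
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  s_true_fun <- function(dirs) two_compartment_signal(dirs, c(0, 0, 1), 1000)
  held_out <- icosphere(3)$vertices
  B_ho <- sh_design_matrix(8, held_out)$B
  s_ho <- s_true_fun(held_out)
  err <- function(lambda) {
    e <- 0
    for (r in 1:20) {
      s_noisy <- s_true_fun(d) + rnorm(82, 0, 0.05)
      cf <- fit_sh_regularized(s_noisy, basis, lambda)
      e <- e + mean((B_ho %*% cf - s_ho)^2)
    }
    e / 20
  }
  expect_lt(err(0.006), err(0))
})

test_that("Funk-Radon transform applies the Legendre-at-zero factors per degree", {
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  cf <- rep(1, 45)
  out <- qball_frt(cf, basis)
  expect_equal(unique(out[basis$l_degree == 0]), 2 * pi)
  expect_equal(unique(out[basis$l_degree == 2]), 2 * pi * (-1 / 2))
  expect_equal(unique(out[basis$l_degree == 4]), 2 * pi * (3 / 8))
  expect_equal(unique(out[basis$l_degree == 6]), 2 * pi * (-5 / 16))
  expect_equal(unique(out[basis$l_degree == 8]), 2 * pi * (35 / 128))
  # isotropic signal -> constant ODF
  iso <- c(3, rep(0, 44))
  odf <- qball_frt(iso, basis)
  vals <- sh_design_matrix(8, icosphere(2)$vertices)$B %*% odf
  expect_lt(diff(range(vals)), 1e-12)
})

test_that("analytic FRT agrees with great-circle numerical integration", {
  set.seed(12)
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  us <- rbind(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3), c(-0.2, 0.9, 0.4))
  us <- us / sqrt(rowSums(us^2))
  for (r in 1:3) {
    cf <- rnorm(45, 0, 0.3)
    odf_cf <- qball_frt(cf, basis)
    ana <- drop(sh_design_matrix(8, us)$B %*% odf_cf)
    num <- vapply(seq_len(nrow(us)), function(i)
      oracle_frt(cf, 8, us[i, ]), numeric(1))
    expect_lt(sqrt(mean((ana - num)^2)) / sqrt(mean(num^2)), 0.02)
  }
})

test_that("single-fiber ODF peaks at the fiber axis within tessellation accuracy", {
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  s <- two_compartment_signal(d, c(0, 0, 1), 3000)
  odf <- qball_frt(fit_sh_regularized(s, basis, 0.006), basis)
  # dense-grid argmax oracle
  sph <- icosphere(4)
  vals <- sh_design_matrix(8, sph$vertices)$B %*% odf
  peak <- sph$vertices[which.max(vals), ]
  expect_lt(180 / pi * acos(min(1, abs(peak[3]))), 3)
})

test_that("peak extraction finds crossings, applies thresholds and handles flat fields", {
  d <- spiral82()$directions
  basis <- sh_design_matrix(8, d)
  sph <- icosphere(3)
  # constant ODF: no strict local maxima, zero peaks
  flat <- extract_peaks(c(1, rep(0, 44)), basis, sph)
  expect_equal(nrow(flat$directions), 0)
  # noise-free 90 degree crossing at b = 3000: two peaks within 5 degrees
  s <- 0.5 * two_compartment_signal(d, c(1, 0, 0), 3000) +
    0.5 * two_compartment_signal(d, c(0, 0, 1), 3000)
  pk <- extract_peaks(qball_frt(fit_sh_regularized(s, basis, 0.006), basis),
                      basis, sph)
  expect_equal(nrow(pk$directions), 2)
  errs <- apply(pk$directions, 1, function(p)
    min(180 / pi * acos(min(1, abs(p[1]))), 180 / pi * acos(min(1, abs(p[3])))))
  expect_true(all(errs < 5))
  # amplitudes sorted descending, separations enforced
  expect_true(all(diff(pk$amplitudes) <= 0))
  # the relative threshold on the min-max normalized ODF drops weak peaks:
  # build a three-peak ODF, find the weakest peak's normalized amplitude,
  # and set the threshold just above it
  odf3 <- qball_frt(fit_sh_regularized(
    0.40 * two_compartment_signal(d, c(1, 0, 0), 3000) +
      0.40 * two_compartment_signal(d, c(0, 0, 1), 3000) +
      0.20 * two_compartment_signal(d, c(0, 1, 0), 3000), basis, 0.006), basis)
  pk_all <- extract_peaks(odf3, basis, sph, relative_threshold = 0)
  expect_equal(nrow(pk_all$directions), 3)
  vals <- sh_design_matrix(8, sph$vertices)$B %*% odf3
  norm_amp <- (pk_all$amplitudes - min(vals)) / (max(vals) - min(vals))
  pk_thr <- extract_peaks(odf3, basis, sph,
                          relative_threshold = norm_amp[3] + 0.01)
  expect_equal(nrow(pk_thr$directions), 2)
})

test_that("peak extraction is rotation equivariant", {
  ang <- 0.7
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  d <- spiral82()$directions
  u <- c(0, 0, 1)
  sph <- icosphere(3)
  basis <- sh_design_matrix(8, d)
  s1 <- two_compartment_signal(d, u, 3000)
  p1 <- extract_peaks(qball_frt(fit_sh_regularized(s1, basis, 0.006), basis),
                      basis, sph)$directions[1, ]
  # rotate directions and fiber jointly
  d_rot <- d %*% t(R)
  basis_rot <- sh_design_matrix(8, d_rot)
  s2 <- two_compartment_signal(d_rot, drop(R %*% u), 3000)
  p2 <- extract_peaks(qball_frt(fit_sh_regularized(s2, basis_rot, 0.006),
                                basis_rot), basis_rot, sph)$directions[1, ]
  # vertex spacing of the 642-point tessellation is about 7.5 degrees
  ang_err <- 180 / pi * acos(min(1, abs(sum(drop(R %*% p1) * p2))))
  expect_lt(ang_err, 7.5)
})

test_that("DTI fit recovers isotropic and anisotropic tensors", {
  scheme <- spiral82()
  scheme$bvalue <- rep(1000, 82)
  D <- scheme$directions
  Dc <- 1.5e-3
  sig <- exp(-1000 * Dc)
  dat <- array(rep(c(rep(sig, 82), 1), each = 8), c(2, 2, 2, 83))
  dat[, , , 1:82] <- sig
  dat[, , , 83] <- 1
  vol <- dwi_volume(dat, scheme, b0_idx = 83L)
  fit <- fit_dti(vol)
  expect_equal(fit$fa, rep(0, 8), tolerance = 1e-8)
  expect_equal(as.vector(fit$eigenvalues), rep(Dc, 24), tolerance = 1e-10)
  # single tensor (1.7, 0.3, 0.3)e-3: closed-form FA
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  s <- exp(-1000 * (D^2 %*% lam))
  dat2 <- array(c(rep(s, each = 1), 1), c(1, 1, 1, 83))
  vol2 <- dwi_volume(dat2, scheme, b0_idx = 83L)
  fit2 <- fit_dti(vol2)
  fa_hand <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fit2$fa, fa_hand, tolerance = 1e-8)
  expect_equal(abs(fit2$v1[1, 1]), 1, tolerance = 1e-6)
})

test_that("noisy isotropic voxels keep FA below the noise floor bound", {
  scheme <- spiral82()
  scheme$bvalue <- rep(1000, 82)
  Dc <- 1.5e-3
  set.seed(13)
  n_vox <- 200
  dat <- array(0, c(n_vox, 1, 1, 83))
  dat[, , , 1:82] <- exp(-1000 * Dc)
  dat[, , , 83] <- 1
  noisy <- add_rician_noise(dat, snr = 40, seed = 14)
  fit <- fit_dti(dwi_volume(noisy, scheme, b0_idx = 83L))
  expect_lt(mean(fit$fa), 0.15)
})
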