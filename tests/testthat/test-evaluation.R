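test_that("MSE map is exact on closed-form cases", {
  x <- array(runif(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  expect_equal(mse_map(x, x)$mean, 0)
  eps <- 0.037
  r <- mse_map(x + eps, x)
  expect_equal(r$mean, eps^2, tolerance = 1e-12)
  expect_equal(r$sd, 0, tolerance = 1e-12)
  expect_error(mse_map(x, x[, , , 1:5]), "mismatch")
})

test_that("MSE increases monotonically as SNR decreases", {
  gt <- build_ground_truth(evaluation_phantom_spec())
  scheme <- spiral82()
  truth <- simulate_signal(gt, scheme, b = 1000)
  dom <- array(gt$domain, gt$dim)
  mse <- vapply(c(100, 50, 30, 20, 10), function(snr)
    mse_map(add_rician_noise(truth, snr = snr, seed = 20 + snr), truth,
            dom)$mean, numeric(1))
  expect_true(all(diff(mse) > 0))
})

test_that("angular error handles identity, antipodes and 45 degree offsets", {
  gt1 <- list(rbind(c(1, 0, 0)))
  mk_est <- function(dirs) structure(list(peaks = list(dirs),
                                          amplitudes = list(rep(1, nrow(dirs))),
                                          counts = nrow(dirs)),
                                     class = "peak_set")
  expect_equal(angular_error(gt1, mk_est(rbind(c(1, 0, 0))))$mean, 0)
  expect_equal(angular_error(gt1, mk_est(rbind(c(-1, 0, 0))))$mean, 0)
  expect_equal(angular_error(gt1, mk_est(rbind(c(1, 1, 0) / sqrt(2))))$mean,
               45, tolerance = 1e-9)
  # no estimated peaks: excluded and counted separately
  r <- angular_error(list(rbind(c(1, 0, 0)), rbind(c(0, 1, 0))),
                     structure(list(peaks = list(rbind(c(1, 0, 0)),
                                                 matrix(0, 0, 3)),
                                    amplitudes = list(1, numeric(0)),
                                    counts = c(1L, 0L)),
                               class = "peak_set"))
  expect_equal(r$n_evaluated, 1)
  expect_equal(r$n_no_peaks, 1)
})

test_that("angular error matching is greedy one-to-one and stays within 0..90", {
  gt <- list(rbind(c(1, 0, 0), c(0, 1, 0)))
  est <- structure(list(peaks = list(rbind(c(0.985, 0.174, 0),
                                           c(0.174, 0.985, 0))),
                        amplitudes = list(c(1, 0.9)), counts = 2L),
                   class = "peak_set")
  r <- angular_error(gt, est)
  expect_equal(r$mean, 10, tolerance = 0.1)
  expect_true(r$mean >= 0 && r$mean <= 90)
})

test_that("fiber count rates sum to 100 and respond to over/under counts", {
  gtc <- c(1L, 1L, 2L, 3L)
  r0 <- fiber_count_rates(gtc, gtc)
  expect_equal(r0$success, 100)
  expect_equal(r0$over_estimation + r0$under_estimation, 0)
  r1 <- fiber_count_rates(pmin(gtc + 1L, 4L), gtc)
  expect_equal(r1$over_estimation, 100)
  r2 <- fiber_count_rates(c(1L, 0L, 3L, 3L), gtc)
  expect_equal(r2$success + r2$over_estimation + r2$under_estimation, 100)
  expect_equal(r2$under_estimation, 25)
  expect_equal(r2$over_estimation, 25)
})

test_that("Otsu threshold matches the exhaustive-scan oracle and splits bimodal data", {
  set.seed(21)
  x <- c(rnorm(400, 0.2, 0.03), rnorm(200, 0.8, 0.05))
  thr <- otsu_threshold(x)
  expect_equal(thr, oracle_otsu(x), tolerance = 1e-12)
  # the threshold separates the two generating modes almost perfectly
  truth <- c(rep(FALSE, 400), rep(TRUE, 200))
  expect_gte(mean((x > thr) == truth), 0.99)
  expect_error(otsu_threshold(rep(1, 10)), "degenerate")
})

test_that("median-Otsu masks recover a bright sphere on a dark field", {
  dims <- c(12, 12, 12)
  ctr <- (dims + 1) / 2
  vol <- array(0.02, c(dims, 5))
  sphere <- array(FALSE, dims)
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    sphere[i, j, k] <- sqrt(sum((c(i, j, k) - ctr)^2)) <= 4
  for (f in 1:5) vol[, , , f][sphere] <- 0.9
  m <- background_foreground_masks(vol)
  expect_identical(m$foreground, sphere)
  expect_true(all(!m$background[sphere]))
  # eroded complement: no background voxel touches the foreground
  expect_true(all(!(m$background & sphere)))
})

test_that("phantom background mask excludes every bundle voxel", {
  gt <- build_ground_truth(evaluation_phantom_spec())
  scheme <- spiral82()
  truth <- simulate_signal(gt, scheme, b = 1000)
  noisy <- add_rician_noise(truth, snr = 40, seed = 22)
  m <- background_foreground_masks(noisy)
  fib <- array(gt$n_fibers > 0, gt$dim)
  expect_true(all(!(m$background & fib)))
})

test_that("SNR estimator is exact on constant signals and calibrated on Rician data", {
  vol <- array(0.5, c(6, 6, 6, 4))
  bg <- array(FALSE, c(6, 6, 6)); bg[1:2, , ] <- TRUE
  roi <- array(FALSE, c(6, 6, 6)); roi[4:6, , ] <- TRUE
  set.seed(23)
  vol[, , , ][array(rep(bg, 4), c(6, 6, 6, 4))] <-
    rnorm(sum(bg) * 4, 0.5, 0.08)
  r <- estimate_snr(vol, roi, bg)
  for (d in 1:4) {
    m <- matrix(vol[, , , d], 216)
    expect_equal(r$per_direction[d], mean(m[roi]) / sd(m[bg]),
                 tolerance = 1e-12)
  }
  expect_error(estimate_snr(vol, array(FALSE, c(6, 6, 6)), bg), "empty")
  # Rician phantom at nominal SNR 40: estimate within 20 percent of the
  # Rayleigh-background oracle (background signal 0, ROI signal S0 = 1)
  snr <- 40; sigma <- 1 / snr
  gt <- build_ground_truth(evaluation_phantom_spec())
  v0 <- simulate_signal(gt, spiral82(), b = 0)     # tissue signal = S0
  noisy <- add_rician_noise(v0, snr = snr, seed = 24)
  dom <- array(gt$domain, gt$dim)
  bg2 <- lopdwi:::.erode3d(!dom)
  est <- estimate_snr(noisy, dom, bg2)
  oracle_snr <- 1 / (sigma * sqrt(2 - pi / 2))   # mean S0 / Rayleigh SD
  expect_lt(abs(est$mean / oracle_snr - 1), 0.2)
})

test_that("denoising raises the estimated SNR of a noisy phantom", {
  gt <- build_ground_truth(evaluation_phantom_spec())
  scheme <- spiral82()
  truth <- simulate_signal(gt, scheme, b = 1000)
  noisy <- add_rician_noise(truth, snr = 20, seed = 25)
  lop <- suppressMessages(denoise_volume(noisy))
  dom <- array(gt$domain, gt$dim)
  bg <- lopdwi:::.erode3d(!dom)
  expect_gt(estimate_snr(lop, dom, bg)$mean,
            estimate_snr(noisy, dom, bg)$mean)
})

test_that("paired t-test matches the textbook formula and flags zero variance", {
  set.seed(26)
  a <- rnorm(30); b <- rnorm(30)
  r <- paired_ttest(a, b)
  o <- oracle_paired_t(a, b)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$zero_variance)
  shift <- paired_ttest(a + 1, a)
  expect_true(shift$zero_variance)
  expect_true(is.na(shift$p))
})
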