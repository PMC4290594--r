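#' Mean squared error against the ground-truth signal
#'
#' Per voxel, the mean over directions of the squared difference between the
#' test signal and the noise-free reference; summarized (mean and SD) over
#' the non-background voxels.
#'
#' @param test a [dwi_volume()] or 4D array.
#' @param truth the noise-free reference [dwi_volume()] or 4D array with the
#'   same dimensions.
#' @param mask logical 3D array of voxels to summarize (e.g. the phantom
#'   domain); default: all voxels.
#' @return A list of class `mse_report`: `per_voxel` (vector over masked
#'   voxels), `mean`, `sd`, `n`.
#' @export
mse_map <- function(test, truth, mask = NULL) {
  xt <- if (inherits(test, "dwi_volume")) test$data else as.array(test)
  xr <- if (inherits(truth, "dwi_volume")) truth$data else as.array(truth)
  if (!identical(dim(xt), dim(xr))) .stopf("dimension mismatch")
  dims <- dim(xt)
  nvox <- prod(dims[1:3])
  per <- rowMeans((matrix(xt, nvox, dims[4]) - matrix(xr, nvox, dims[4]))^2)
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  pv <- per[vox]
  structure(list(per_voxel = pv, mean = mean(pv), sd = stats::sd(pv),
                 n = length(pv)),
            class = "mse_report")
}

#' Angular error between ground-truth and estimated fiber peaks
#'
#' For each voxel with at least one ground-truth fiber and at least one
#' estimated peak, estimated peaks are matched one-to-one to ground-truth
#' directions greedily by smallest symmetrized angle; each matched pair
#' contributes `(180/pi) * acos(|p_gt . p_est|)` degrees (the absolute dot
#' product encodes the antipodal fiber symmetry, so errors lie in
#' \[0, 90\] degrees). The voxel value is the mean over matched ground-truth
#' fibers. Voxels with no estimated peaks are excluded and counted
#' separately (they contribute to the under-estimation rate, not here).
#'
#' @param gt_dirs list of k x 3 matrices of ground-truth fiber directions
#'   (one per voxel), or a `ground_truth` object plus `voxels`.
#' @param est a `peak_set` from [extract_peaks()]/[qball_peaks()], aligned
#'   with `gt_dirs`.
#' @return A list of class `angular_error_report`: `per_voxel` (degrees, NA
#'   where no estimate), `mean`, `sd`, `n_evaluated`, `n_no_peaks`.
#' @export
angular_error <- function(gt_dirs, est) {
  if (inherits(gt_dirs, "ground_truth")) {
    vox <- attr(est, "voxels")
    if (is.null(vox)) .stopf("peak set lacks voxel indices")
    gt_dirs <- lapply(vox, function(v) {
      k <- gt_dirs$n_fibers[v]
      gt_dirs$directions[v, seq_len(k), , drop = FALSE][1, , , drop = TRUE] |>
        matrix(nrow = k, ncol = 3)
    })
  }
  stopifnot(length(gt_dirs) == length(est$peaks))
  per <- rep(NA_real_, length(gt_dirs))
  for (v in seq_along(gt_dirs)) {
    G <- gt_dirs[[v]]
    E <- est$peaks[[v]]
    if (is.null(G) || nrow(G) == 0) next
    if (is.null(E) || nrow(E) == 0) { per[v] <- NA_real_; next }
    ang <- 180 / pi * acos(.clamp(abs(G %*% t(E))))
    errs <- numeric(0)
    while (length(errs) < min(nrow(G), ncol(ang)) && length(ang) > 0) {
      ij <- arrayInd(which.min(ang), dim(ang))
      errs <- c(errs, ang[ij[1], ij[2]])
      ang[ij[1], ] <- Inf
      ang[, ij[2]] <- Inf
      if (all(is.infinite(ang))) break
    }
    per[v] <- mean(errs)
  }
  ok <- !is.na(per) & vapply(gt_dirs, function(g) !is.null(g) && nrow(g) > 0,
                             logical(1))
  structure(list(per_voxel = per, mean = mean(per[ok]), sd = stats::sd(per[ok]),
                 n_evaluated = sum(ok),
                 n_no_peaks = sum(is.na(per) &
                                    vapply(gt_dirs, function(g)
                                      !is.null(g) && nrow(g) > 0, logical(1)))),
            class = "angular_error_report")
}

#' Fiber-count success, over- and under-estimation rates
#'
#' Over the fiber-containing voxels, the percentage whose estimated peak
#' count exceeds (over), falls short of (under) or equals (success) the true
#' fiber count. Under the count-equality definition the three rates sum to
#' 100. Voxels with zero estimated peaks count as under-estimation.
#'
#' @param est a `peak_set` (with `counts`), or an integer vector of
#'   estimated counts.
#' @param gt a `ground_truth` (true counts taken at the peak set's `voxels`
#'   attribute) or an integer vector of true counts.
#' @return A list of class `count_rates`: `success`, `over_estimation`,
#'   `under_estimation` (percent), `n`.
#' @export
fiber_count_rates <- function(est, gt) {
  ec <- if (inherits(est, "peak_set")) est$counts else as.integer(est)
  tc <- if (inherits(gt, "ground_truth")) {
    vox <- attr(est, "voxels")
    if (!is.null(vox)) gt$n_fibers[vox] else gt$n_fibers
  } else as.integer(gt)
  stopifnot(length(ec) == length(tc))
  keep <- tc > 0
  ec <- ec[keep]; tc <- tc[keep]
  n <- length(ec)
  structure(list(success = 100 * sum(ec == tc) / n,
                 over_estimation = 100 * sum(ec > tc) / n,
                 under_estimation = 100 * sum(ec < tc) / n,
                 n = n),
            class = "count_rates")
}

#' @export
print.count_rates <- function(x, ...) {
  cat(sprintf("Fiber counts over %d voxels: success %.1f%%, over %.1f%%, under %.1f%%\n",
              x$n, x$success, x$over_estimation, x$under_estimation))
  invisible(x)
}

#' Otsu threshold of a numeric array
#'
#' Exhaustive maximization of the between-class variance over a 256-bin
#' histogram of the data range; returns the threshold value (bin upper
#' edge).
#'
#' @param x numeric array or vector.
#' @param n_bins histogram resolution.
#' @return Scalar threshold; values > threshold are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) <= 0) .stopf("degenerate (constant) image")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  br[which.max(bcv) + 1]
}

# 6-neighbour binary erosion of a 3D logical array; voxels outside the
# volume are treated as FALSE
.erode3d <- function(m) {
  d <- dim(m)
  out <- m
  for (ax in 1:3) for (by in c(-1, 1)) {
    idx_src <- lapply(d, seq_len)
    idx_src[[ax]] <- idx_src[[ax]] + by
    pad <- array(FALSE, d)
    ok <- idx_src[[ax]] >= 1 & idx_src[[ax]] <= d[ax]
    sel_dst <- lapply(d, seq_len); sel_dst[[ax]] <- which(ok)
    sel_src <- lapply(d, seq_len); sel_src[[ax]] <- idx_src[[ax]][ok]
    pad[sel_dst[[1]], sel_dst[[2]], sel_dst[[3]]] <-
      m[sel_src[[1]], sel_src[[2]], sel_src[[3]]]
    out <- out & pad
  }
  out
}

#' Median-Otsu foreground/background masks
#'
#' Computes the voxel-wise median image across directions, thresholds it
#' with [otsu_threshold()] to obtain the foreground, and takes the
#' complement eroded by one voxel (6-neighborhood) as background.
#'
#' @param vol a [dwi_volume()] or 4D array.
#' @return A list with logical 3D arrays `foreground` and `background`.
#' @export
background_foreground_masks <- function(vol) {
  x <- if (inherits(vol, "dwi_volume")) vol$data else as.array(vol)
  dims <- dim(x)
  med <- array(apply(matrix(x, prod(dims[1:3]), dims[4]), 1, stats::median),
               dims[1:3])
  thr <- otsu_threshold(med)
  fg <- med > thr
  bg <- .erode3d(!fg)
  list(foreground = fg, background = bg)
}

#' Estimate SNR from an ROI and a background mask
#'
#' Per gradient direction, SNR is the mean signal over the region of
#' interest divided by the standard deviation over background voxels; the
#' report carries the per-direction values and their mean and SD.
#'
#' @param vol a [dwi_volume()] or 4D array.
#' @param roi logical 3D array, region of interest (nonempty).
#' @param background logical 3D array, noise-only region (nonempty).
#' @return A list of class `snr_report`: `per_direction`, `mean`, `sd`.
#' @export
estimate_snr <- function(vol, roi, background) {
  x <- if (inherits(vol, "dwi_volume")) vol$data else as.array(vol)
  dims <- dim(x)
  roi <- which(as.logical(roi)); bg <- which(as.logical(background))
  if (length(roi) == 0 || length(bg) == 0) .stopf("empty mask")
  m <- matrix(x, prod(dims[1:3]), dims[4])
  snr_d <- vapply(seq_len(dims[4]), function(d)
    mean(m[roi, d]) / stats::sd(m[bg, d]), numeric(1))
  structure(list(per_direction = snr_d, mean = mean(snr_d),
                 sd = stats::sd(snr_d)),
            class = "snr_report")
}

#' Paired t-test with zero-variance guard
#'
#' Standard two-sided paired t-test on the differences `a - b`. When the
#' differences have zero variance the test statistic is undefined: the
#' result is flagged, with `t = 0, p = 1` if the differences are identically
#' zero and `p = NA` otherwise.
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @return A list with `t`, `p`, `mean_diff`, `df`, `zero_variance`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(list(t = 0, p = 1, mean_diff = 0, df = length(d) - 1,
                  zero_variance = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, mean_diff = mean(d),
                df = length(d) - 1, zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter),
       zero_variance = FALSE)
}
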