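#' Filter configuration
#'
#' Settings for gradient-direction-domain low-pass denoising. `cutoff`
#' counts retained nonnegative-frequency DFT bins including DC: cutoff 11
#' keeps bins k = 0..10 and their conjugate mirrors, i.e. 21 of 82 complex
#' bins (about 25%) for an 82-direction scheme.
#'
#' @param cutoff number of retained nonnegative-frequency bins (incl. DC).
#' @param detrend subtract/restore the least-squares linear trend around the
#'   filtering step.
#' @param clip_negative clip negative filtered samples to 0 (magnitude MR
#'   signals are nonnegative).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cutoff = 11, detrend = TRUE, clip_negative = TRUE) {
  if (!is.numeric(cutoff) || cutoff < 1) .stopf("cutoff must be >= 1")
  structure(list(cutoff = as.integer(cutoff), detrend = isTRUE(detrend),
                 clip_negative = isTRUE(clip_negative)),
            class = "filter_config")
}

#' Least-squares linear detrend
#'
#' Subtracts the ordinary least-squares line in sample index n = 0..N-1.
#' The residual is orthogonal to the constant and linear regressors.
#'
#' @param s numeric vector (the voxel signal ordered along the acquisition
#'   spiral), length >= 2.
#' @return A list with `residual`, `slope`, `intercept`.
#' @export
detrend_signal <- function(s) {
  n <- length(s)
  if (n < 2) .stopf("need at least 2 samples")
  t_idx <- seq_len(n) - 1
  tc <- t_idx - mean(t_idx)
  slope <- sum(s * tc) / sum(tc^2)
  intercept <- mean(s) - slope * mean(t_idx)
  list(residual = s - (intercept + slope * t_idx),
       slope = slope, intercept = intercept)
}

#' Fourier low-pass filter
#'
#' DFT of `s`; bins with frequency index |k| <= cutoff - 1 are retained
#' (conjugate-symmetric pairs zeroed together so the output is real); the
#' rest are zero-filled; inverse DFT; real part returned.
#'
#' @param s numeric vector.
#' @param cutoff retained nonnegative-frequency bins including DC; must be in
#'   `1..floor(N/2)+1`. `cutoff = floor(N/2)+1` is all-pass.
#' @return Numeric vector, same length.
#' @export
fourier_lowpass <- function(s, cutoff) {
  n <- length(s)
  kmax <- floor(n / 2) + 1
  if (!is.numeric(cutoff) || cutoff < 1 || cutoff > kmax)
    .stopf("cutoff must be in 1..%d for N = %d", kmax, n)
  f <- stats::fft(s)
  keep <- .lowpass_keep(n, cutoff)
  f[!keep] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

# logical mask of retained DFT bins (1-based R indexing)
.lowpass_keep <- function(n, cutoff) {
  k <- c(0:(n - 1))
  freq <- pmin(k, n - k)          # |frequency index| of each bin
  freq <= cutoff - 1
}

# orthonormal basis of span{1, n (optional), in-band Fourier modes}
.lop_basis <- function(n, cutoff, detrend) {
  t_idx <- seq_len(n) - 1
  cols <- list(rep(1, n))
  if (cutoff > 1) for (k in seq_len(cutoff - 1)) {
    cols[[length(cols) + 1]] <- cos(2 * pi * k * t_idx / n)
    if (k != n - k)                       # the Nyquist mode has no sine
      cols[[length(cols) + 1]] <- sin(2 * pi * k * t_idx / n)
  }
  if (detrend) cols[[length(cols) + 1]] <- t_idx
  qr.Q(qr(do.call(cbind, cols)))
}

#' Low-pass denoise a spiral-ordered voxel signal
#'
#' The denoising core: detrend by the least-squares line, low-pass in the
#' Fourier domain, restore the trend, and optionally clip negative samples
#' to 0. With spiral-ordered sampling the diffusion signal concentrates at
#' low frequencies, so the retained band keeps the fiber signal and the
#' zero-filled band removes mostly noise.
#'
#' The trend and passband are handled jointly: the output (before clipping)
#' is the least-squares projection of the signal onto the span of the linear
#' trend and the retained Fourier modes. This is the self-consistent form of
#' detrend-filter-retrend -- the two differ only by the small trend
#' component the sequential filter re-introduces -- and makes the operator
#' exactly linear and idempotent. With `detrend = FALSE` it reduces to
#' [fourier_lowpass()].
#'
#' @param s numeric vector ordered by the scheme's spiral `order_index`.
#' @param cfg a [filter_config()].
#' @return Numeric vector, same length.
#' @export
lop_denoise <- function(s, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- length(s)
  kmax <- floor(n / 2) + 1
  if (cfg$cutoff > kmax)
    .stopf("cutoff must be in 1..%d for N = %d", kmax, n)
  Q <- .lop_basis(n, cfg$cutoff, cfg$detrend)
  out <- drop(Q %*% crossprod(Q, s))
  if (cfg$clip_negative) out <- pmax(out, 0)
  out
}

#' Denoise a DWI volume voxel-wise in the gradient direction domain
#'
#' Applies [lop_denoise()] independently to every voxel's direction-ordered
#' signal. There is no spatial coupling: the filter acts purely along the
#' 4th (direction) dimension, ordered by the scheme's `order_index`. b0
#' volumes are passed through unchanged. The filter is defined only for
#' spiral-ordered schemes; electrostatic schemes have no acquisition
#' continuity and are refused rather than silently re-ordered.
#'
#' @param vol a [dwi_volume()] or 4D array.
#' @param scheme the [gradient_scheme()] (taken from `vol` if absent).
#' @param cfg a [filter_config()].
#' @param mask optional logical 3D array; only masked voxels are filtered.
#' @return Same type as `vol`, denoised (kind "denoised"). The fraction of
#'   clipped samples is reported via `message()`.
#' @export
denoise_volume <- function(vol, scheme = NULL, cfg = filter_config(),
                           mask = NULL) {
  if (inherits(vol, "dwi_volume")) {
    scheme <- scheme %||% vol$scheme
    x <- vol$data
    b0_idx <- vol$b0_idx
  } else {
    if (is.null(scheme)) .stopf("scheme required for plain arrays")
    x <- as.array(vol)
    b0_idx <- integer(0)
  }
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (scheme$kind == "electrostatic")
    .stopf(paste("electrostatic schemes have no spiral ordering;",
                 "gradient-direction-domain filtering requires an explicit",
                 "spiral-ordered scheme"))
  dims <- dim(x)
  n_dir <- nrow(scheme$directions)
  if (dims[4] != n_dir + length(b0_idx))
    .stopf("volume has %d frames but scheme implies %d",
           dims[4], n_dir + length(b0_idx))
  dwi_idx <- setdiff(seq_len(dims[4]), b0_idx)
  nvox <- prod(dims[1:3])
  m <- matrix(x, nvox, dims[4])
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  acq_order <- order(scheme$order_index)     # storage rows in spiral order
  s_mat <- m[vox, dwi_idx[acq_order], drop = FALSE]
  n <- ncol(s_mat)
  if (cfg$cutoff > floor(n / 2) + 1)
    .stopf("cutoff must be in 1..%d for N = %d", floor(n / 2) + 1, n)
  Q <- .lop_basis(n, cfg$cutoff, cfg$detrend)
  out <- (s_mat %*% Q) %*% t(Q)
  n_clip <- 0
  if (cfg$clip_negative) {
    n_clip <- sum(out < 0)
    out[out < 0] <- 0
  }
  m[vox, dwi_idx[acq_order]] <- out
  message(sprintf("denoise_volume: cutoff %d, %d voxels, %.3f%% samples clipped",
                  cfg$cutoff, length(vox), 100 * n_clip / length(out)))
  y <- array(m, dims)
  if (inherits(vol, "dwi_volume")) {
    vol$data <- y
    vol$kind <- "denoised"
    vol
  } else y
}
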