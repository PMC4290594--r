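#' Read a DWI dataset from NIfTI + FSL gradient table
#'
#' Loads a 4D NIfTI volume together with FSL-dialect `bval` / `bvec` files.
#' Volumes with `b < b0_threshold` s/mm^2 are identified as unweighted (b0);
#' the remaining bvec columns are normalized to unit length. Both the FSL
#' 3-row and the transposed 3-column bvec layouts are accepted. An optional
#' order file (one 0-based integer per weighted volume) supplies the spiral
#' acquisition position when volume storage order differs from it.
#'
#' @param nifti_path path to a `.nii`/`.nii.gz` 4D volume.
#' @param bval_path,bvec_path gradient table files.
#' @param order_path optional text file of 0-based spiral positions.
#' @param kind scheme kind tag.
#' @param b0_threshold b-value below which a volume counts as b0.
#' @return An object of class `dwi_dataset`: `data` (4D array), `scheme`
#'   ([gradient_scheme()], weighted directions in storage order), `b0_idx`
#'   (frame indices of b0 volumes), `bvals` (all frames), `affine`
#'   (4x4 voxel-to-world matrix), `voxel_size`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, order_path = NULL,
                     kind = "exact_spiral", b0_threshold = 50) {
  img <- RNifti::readNifti(nifti_path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # drop NIfTI header attributes
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  bvals <- as.numeric(utils::read.table(bval_path))
  bvec <- .parse_bvec(as.matrix(utils::read.table(bvec_path)))
  if (nrow(bvec) != length(bvals) || dim(data)[4] != length(bvals))
    .stopf("gradient table (%d) does not match volume count (%d)",
           length(bvals), dim(data)[4])
  b0 <- bvals < b0_threshold
  dirs <- bvec[!b0, , drop = FALSE]
  dirs <- .unit_rows(dirs)
  order_index <- NULL
  if (!is.null(order_path)) {
    order_index <- as.integer(scan(order_path, quiet = TRUE))
    if (length(order_index) != nrow(dirs))
      .stopf("order file length does not match weighted volume count")
  }
  scheme <- gradient_scheme(dirs, bvalue = bvals[!b0],
                            order_index = order_index, kind = kind,
                            n_b0 = sum(b0))
  pix <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  structure(list(data = data, scheme = scheme, b0_idx = which(b0),
                 bvals = bvals, affine = unclass(RNifti::xform(img)),
                 voxel_size = pix[1:3]),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf("DWI dataset: %s grid, %d weighted + %d b0 volumes\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              nrow(x$scheme$directions), length(x$b0_idx)))
  invisible(x)
}

#' Write a DWI dataset (or volume) as NIfTI + FSL gradient table
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` (FSL 3-row
#' layout; b0 frames get zero vectors) and, when the scheme carries a
#' non-trivial acquisition order, `<prefix>.order` with 0-based spiral
#' positions.
#'
#' @param x a `dwi_dataset` or [dwi_volume()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(x, prefix) {
  data <- x$data
  scheme <- x$scheme
  b0_idx <- x$b0_idx %||% integer(0)
  n_frames <- dim(data)[4]
  bvals <- numeric(n_frames)
  vecs <- matrix(0, n_frames, 3)
  dwi_idx <- setdiff(seq_len(n_frames), b0_idx)
  bvals[dwi_idx] <- scheme$bvalue
  vecs[dwi_idx, ] <- scheme$directions
  vs <- x$voxel_size %||% 1
  if (length(vs) == 1) vs <- rep(vs, 3)
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- c(vs, 1)
  RNifti::writeNifti(img, sprintf("%s.nii.gz", prefix))
  write(t(vecs)[1, ], sprintf("%s.bvec", prefix), ncolumns = n_frames)
  write(t(vecs)[2, ], sprintf("%s.bvec", prefix), ncolumns = n_frames,
        append = TRUE)
  write(t(vecs)[3, ], sprintf("%s.bvec", prefix), ncolumns = n_frames,
        append = TRUE)
  write(bvals, sprintf("%s.bval", prefix), ncolumns = n_frames)
  if (!identical(scheme$order_index, seq_len(nrow(scheme$directions)) - 1L))
    write(scheme$order_index, sprintf("%s.order", prefix),
          ncolumns = length(scheme$order_index))
  invisible(prefix)
}

#' Concatenate DWI datasets
#'
#' Appends the volumes and gradient tables of several datasets acquired on
#' the same grid into one dataset (concatenated, not averaged); b0 volumes
#' are retained. All inputs must share grid dimensions and affine.
#'
#' @param datasets list of `dwi_dataset` objects.
#' @return A single `dwi_dataset`.
#' @export
concatenate_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  if (length(datasets) == 1) return(datasets[[1]])
  ref <- datasets[[1]]
  d3 <- dim(ref$data)[1:3]
  for (ds in datasets[-1]) {
    if (!identical(dim(ds$data)[1:3], d3))
      .stopf("grid mismatch between datasets")
    if (!is.null(ref$affine) && !is.null(ds$affine) &&
        max(abs(ref$affine - ds$affine)) > 1e-4)
      .stopf("affine mismatch between datasets")
  }
  n4 <- vapply(datasets, function(d) dim(d$data)[4], integer(1))
  data <- array(0, c(d3, sum(n4)))
  off <- 0L
  b0_idx <- integer(0)
  dirs <- NULL; bv <- numeric(0)
  for (ds in datasets) {
    data[, , , off + seq_len(dim(ds$data)[4])] <- ds$data
    b0_idx <- c(b0_idx, off + ds$b0_idx)
    dirs <- rbind(dirs, ds$scheme$directions)
    bv <- c(bv, ds$scheme$bvalue)
    off <- off + dim(ds$data)[4]
  }
  message(sprintf("concatenated %d datasets: %d weighted volumes, %d b0",
                  length(datasets), nrow(dirs), length(b0_idx)))
  structure(list(data = data,
                 scheme = gradient_scheme(dirs, bvalue = bv,
                                          kind = ref$scheme$kind,
                                          n_b0 = length(b0_idx)),
                 b0_idx = b0_idx,
                 bvals = unlist(lapply(datasets, function(d) d$bvals)),
                 affine = ref$affine, voxel_size = ref$voxel_size),
            class = "dwi_dataset")
}

#' Write a reproducibility manifest
#'
#' Serializes run arguments, seeds and package version to JSON so a
#' deterministic stage can be re-run identically.
#'
#' @param path output JSON path.
#' @param args named list of run arguments.
#' @param seed RNG seed used (if any).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, args, seed = NULL) {
  manifest <- list(
    package = "lopdwi",
    version = as.character(utils::packageVersion("lopdwi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    args = args)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
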