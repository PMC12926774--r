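#' 4D functional volume series
#'
#' Container for a 4D fMRI acquisition on an (x, y, slice, time) grid, with
#' in-plane and through-plane voxel sizes, the volume repetition interval
#' (TR), and optional per-slice acquisition offsets. Slices are the third
#' voxel axis throughout the package: every "slice-wise" operation iterates
#' that axis.
#'
#' @param data Real-valued 4D array indexed (x, y, slice, time).
#' @param voxel_size_mm Numeric triple of positive voxel sizes in mm.
#' @param tr_s Positive volume repetition interval in seconds.
#' @param slice_times_s Optional per-slice acquisition offsets (seconds)
#'   within a volume; defaults to 0 for every slice.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm, tr_s, slice_times_s = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, slice, time)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("time dimension must have length >= 2", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive values", call. = FALSE)
  tr_s <- as.numeric(tr_s)
  if (length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a single positive value", call. = FALSE)
  n_slices <- dim(data)[3]
  if (is.null(slice_times_s)) slice_times_s <- rep(0, n_slices)
  if (length(slice_times_s) != n_slices)
    stop("`slice_times_s` must have one entry per slice", call. = FALSE)
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         slice_times_s = as.numeric(slice_times_s)),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %g x %g x %g mm, TR = %g s\n",
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$tr_s))
  invisible(x)
}

#' @rdname volume_series
#' @param x Object to test.
#' @export
is_volume_series <- function(x) inherits(x, "volume_series")

n_timepoints <- function(v) dim(v$data)[4]
n_slices <- function(v) dim(v$data)[3]

#' Binary mask on a 3D voxel grid
#'
#' @param data Binary (0/1 or logical) 3D array on the same (x, y, slice)
#'   grid as an associated [volume_series()].
#' @param voxel_size_mm Numeric triple of positive voxel sizes in mm.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, voxel_size_mm) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array (x, y, slice)", call. = FALSE)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive values", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, %d set\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @rdname mask_volume
#' @param x Object to test.
#' @export
is_mask_volume <- function(x) inherits(x, "mask_volume")

# in-plane (x, y) coordinates of set voxels on one slice, robust to
# degenerate dimensions that base indexing would drop
slice_voxels <- function(m3d, z) {
  sl <- array(m3d[, , z], dim(m3d)[1:2])
  which(sl == 1L, arr.ind = TRUE)
}

check_same_grid <- function(a_dim, b_dim, what = "mask") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s grid (%s) does not match (%s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a 4D NIfTI volume
#'
#' Loads a 4D NIfTI-1 image; voxel sizes and the TR are taken from the
#' header `pixdim` field (time is the 4th axis).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param slice_times_s Optional per-slice acquisition offsets in seconds.
#' @return A [volume_series()].
#' @export
read_volume <- function(path, slice_times_s = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("could not read NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D image, got %d dimensions", length(d)),
         call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  pd <- hdr$pixdim
  volume_series(array(as.numeric(img), dim = d),
                voxel_size_mm = abs(pd[2:4]), tr_s = pd[5],
                slice_times_s = slice_times_s)
}

#' Write a volume series to NIfTI
#'
#' @param v A [volume_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume_series(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- c(v$voxel_size_mm, v$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI mask
#'
#' Non-binary maps are thresholded with [binarize_mask()] at `threshold`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D map.
#' @param threshold Inclusion threshold (strict `>`), default 0.5.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("could not read NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected a 3D image for a mask", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  binarize_mask(array(as.numeric(img), dim = d), threshold = threshold,
                voxel_size_mm = abs(hdr$pixdim[2:4]))
}

#' Write a mask to NIfTI
#'
#' @param m A [mask_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  stopifnot(is_mask_volume(m))
  img <- RNifti::asNifti(m$data)
  RNifti::pixdim(img) <- m$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold a probabilistic map into a binary mask
#'
#' A voxel is included iff its value is strictly greater than `threshold`
#' (the convention used for warped tissue masks thresholded at 0.5).
#'
#' @param map Real 3D array, or a [mask_volume()]-like list with `data`.
#' @param threshold Threshold; default 0.5.
#' @param voxel_size_mm Voxel sizes attached to the result (default 1 mm
#'   isotropic when `map` is a bare array).
#' @return A [mask_volume()].
#' @export
binarize_mask <- function(map, threshold = 0.5, voxel_size_mm = c(1, 1, 1)) {
  if (is_mask_volume(map) || (is.list(map) && !is.null(map$data))) {
    voxel_size_mm <- map$voxel_size_mm
    map <- map$data
  }
  map <- as.array(map)
  if (any(!is.finite(map)))
    stop("map contains non-finite values", call. = FALSE)
  mask_volume((map > threshold) * 1L, voxel_size_mm = voxel_size_mm)
}

#' Keep the first n volumes of a series
#'
#' Truncation takes the initial contiguous segment of the run; header
#' metadata (voxel sizes, TR, slice times) is preserved. Used to put runs of
#' different lengths on a common footing before parallel analysis.
#'
#' @param v A [volume_series()].
#' @param n Number of volumes to keep (1 <= n <= T).
#' @return A [volume_series()] with `n` timepoints.
#' @export
truncate_volume <- function(v, n) {
  stopifnot(is_volume_series(v))
  n <- as.integer(n)
  t_len <- n_timepoints(v)
  if (n < 1L || n > t_len)
    stop(sprintf("`n` must be in [1, %d], got %d", t_len, n), call. = FALSE)
  out <- v
  out$data <- v$data[, , , seq_len(n), drop = FALSE]
  out
}
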