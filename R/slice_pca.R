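#' Extract the noise-ROI timeseries matrix for one slice
#'
#' Gathers every ROI voxel timeseries on the given slice into a T x V
#' matrix (rows: timepoints, columns: voxels), with columns ordered by
#' (x, y) voxel coordinate lexicographically. Zero-variance voxels carry no
#' usable signal and are dropped (and recorded in `dropped_coords`).
#'
#' @param v A [volume_series()].
#' @param roi A [mask_volume()] on the same grid.
#' @param slice_index 1-based slice index.
#' @return An object of class `slice_matrix` with fields `values` (T x V),
#'   `voxel_coords` (V x 2 integer matrix of (x, y)), `slice_index`,
#'   `dropped_coords`.
#' @export
extract_slice_matrix <- function(v, roi, slice_index) {
  stopifnot(is_volume_series(v), is_mask_volume(roi))
  check_same_grid(dim(v$data)[1:3], dim(roi$data), "ROI")
  slice_index <- as.integer(slice_index)
  d <- dim(v$data)
  if (slice_index < 1L || slice_index > d[3])
    stop("`slice_index` out of range", call. = FALSE)
  idx <- slice_voxels(roi$data, slice_index)
  if (nrow(idx) > 0) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(idx) < 2L)
    stop(sprintf("slice %d has fewer than 2 usable ROI voxels", slice_index),
         call. = FALSE)
  t_len <- d[4]
  vals <- matrix(
    v$data[cbind(rep(idx[, 1], each = t_len),
                 rep(idx[, 2], each = t_len),
                 slice_index,
                 rep.int(seq_len(t_len), nrow(idx)))],
    nrow = t_len
  )
  vars <- apply(vals, 2, stats::var)
  keep <- vars > 0
  dropped <- idx[!keep, , drop = FALSE]
  vals <- vals[, keep, drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  if (ncol(vals) < 2L)
    stop(sprintf("slice %d has fewer than 2 non-constant ROI voxels",
                 slice_index), call. = FALSE)
  slice_matrix(vals, idx, slice_index, dropped)
}

#' @rdname extract_slice_matrix
#' @param values T x V numeric matrix.
#' @param voxel_coords V x 2 integer matrix of in-plane coordinates.
#' @param dropped_coords Coordinates of excluded zero-variance voxels.
#' @export
slice_matrix <- function(values, voxel_coords, slice_index,
                         dropped_coords = matrix(integer(), 0, 2)) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("slice matrix contains non-finite values", call. = FALSE)
  structure(list(values = values,
                 voxel_coords = voxel_coords,
                 slice_index = as.integer(slice_index),
                 dropped_coords = dropped_coords),
            class = "slice_matrix")
}

#' @export
print.slice_matrix <- function(x, ...) {
  cat(sprintf("<slice_matrix> slice %d: %d timepoints x %d voxels\n",
              x$slice_index, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Slice-wise principal component analysis by SVD
#'
#' Columns are mean-centered (not variance-scaled) and decomposed by
#' singular value decomposition. Eigenvalues are the squared singular
#' values divided by (T - 1), i.e. the eigenvalues of the sample covariance
#' of the voxel timeseries; N = min(T - 1, V) components are returned.
#' Component signs are fixed so each component's largest-magnitude loading
#' is positive, making results deterministic across platforms.
#'
#' @param m A [slice_matrix()] (or bare T x V matrix).
#' @return An object of class `pc_result` with `scores` (T x N), `eigenvalues`
#'   (descending), `singular_values`, `loadings` (V x N), `n_components`,
#'   `slice_index`.
#' @export
slice_pca <- function(m) {
  if (is.matrix(m)) m <- slice_matrix(m, cbind(seq_len(ncol(m)), 1L), 0L)
  stopifnot(inherits(m, "slice_matrix"))
  x <- m$values
  t_len <- nrow(x)
  v_len <- ncol(x)
  if (t_len < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (v_len < 2L) stop("need at least 2 voxels", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x), "-")
  n <- min(t_len - 1L, v_len)
  sv <- svd(xc, nu = n, nv = n)
  d <- sv$d[seq_len(n)]
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(n)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  structure(list(scores = sv$u %*% diag(d, n, n),
                 eigenvalues = d^2 / (t_len - 1L),
                 singular_values = d,
                 loadings = sv$v,
                 n_components = n,
                 slice_index = m$slice_index),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d components (slice %d); top eigenvalues: %s\n",
              x$n_components, x$slice_index,
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Select leading principal components as nuisance regressors
#'
#' Takes the first `k` component score timeseries and normalizes each to
#' unit sample variance (normalization only conditions the design matrix;
#' it does not change fitted models). Columns are labeled `PC1..PCk`,
#' group `"pca"`.
#'
#' @param pc A [slice_pca()] result.
#' @param k Number of components to keep (0 <= k <= N).
#' @return A [regressor_table()] with `k` columns.
#' @export
pc_regressors <- function(pc, k) {
  stopifnot(inherits(pc, "pc_result"))
  k <- as.integer(k)
  if (k < 0L || k > pc$n_components)
    stop(sprintf("`k` must be in [0, %d]", pc$n_components), call. = FALSE)
  if (k == 0L) return(regressor_table())
  cols <- lapply(seq_len(k), function(i) {
    s <- pc$scores[, i]
    s / stats::sd(s)
  })
  names(cols) <- paste0("PC", seq_len(k))
  regressor_table(cols, "pca")
}
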