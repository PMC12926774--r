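#' Noise-ROI construction parameters
#'
#' @param dilation_mm In-plane dilation radius in mm applied to the
#'   cord/CSF mask (default 18 mm, the distance to the approximate image
#'   boundary for reduced-FOV cervical acquisitions).
#' @param edge_trim_voxels Width (in voxels) of the in-plane field-of-view
#'   border removed from the ROI (default 3).
#' @return An object of class `noise_roi_spec`.
#' @export
noise_roi_spec <- function(dilation_mm = 18, edge_trim_voxels = 3) {
  if (!is.finite(dilation_mm) || dilation_mm <= 0)
    stop("`dilation_mm` must be positive", call. = FALSE)
  edge_trim_voxels <- as.integer(edge_trim_voxels)
  if (edge_trim_voxels < 0)
    stop("`edge_trim_voxels` must be >= 0", call. = FALSE)
  structure(list(dilation_mm = dilation_mm,
                 edge_trim_voxels = edge_trim_voxels),
            class = "noise_roi_spec")
}

#' In-plane morphological dilation of a mask
#'
#' Dilates a binary mask slice-by-slice with an elliptical structuring
#' element whose semi-axes are `radius_mm` converted to whole voxels on
#' each in-plane axis independently (rounded to the nearest voxel; the
#' footprint test uses squared-voxel-normalized distance <= 1). There is no
#' cross-slice dilation: slices are thick relative to the in-plane
#' resolution and the whole pipeline is slice-wise.
#'
#' @param mask A [mask_volume()].
#' @param radius_mm Positive dilation radius in mm.
#' @return A dilated [mask_volume()].
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(is_mask_volume(mask))
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive", call. = FALSE)
  if (sum(mask$data) == 0)
    stop("mask is empty on every slice", call. = FALSE)
  rx <- round(radius_mm / mask$voxel_size_mm[1])
  ry <- round(radius_mm / mask$voxel_size_mm[2])
  if (rx == 0 && ry == 0) {
    warning("dilation radius rounds to 0 voxels; mask returned unchanged")
    return(mask)
  }
  d <- dim(mask$data)
  # elliptical footprint offsets, squared-normalized distance <= 1
  offs <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  keep <- (offs$dx / max(rx, 1))^2 + (offs$dy / max(ry, 1))^2 <= 1
  offs <- offs[keep, , drop = FALSE]
  out <- array(0L, d)
  for (z in seq_len(d[3])) {
    sl <- mask$data[, , z]
    if (!any(sl == 1L)) next
    idx <- which(sl == 1L, arr.ind = TRUE)
    acc <- matrix(FALSE, d[1], d[2])
    for (k in seq_len(nrow(offs))) {
      xs <- idx[, 1] + offs$dx[k]
      ys <- idx[, 2] + offs$dy[k]
      ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
      acc[cbind(xs[ok], ys[ok])] <- TRUE
    }
    out[, , z] <- acc * 1L
  }
  mask_volume(out, mask$voxel_size_mm)
}

#' Build the noise ROI outside the spinal cord and CSF
#'
#' The cord/CSF mask is dilated in-plane by `spec$dilation_mm`, the cord/CSF
#' mask itself is subtracted, and an `spec$edge_trim_voxels`-wide border on
#' both in-plane axes is removed. Voxels in the result are expected to carry
#' only non-neural fluctuations (muscle, vessels, fat, air) and feed the
#' slice-wise PCA.
#'
#' @param cord_csf_mask A [mask_volume()] covering spinal cord plus CSF.
#' @param spec A [noise_roi_spec()].
#' @return A [mask_volume()], disjoint from `cord_csf_mask` by construction.
#' @export
build_noise_roi <- function(cord_csf_mask, spec = noise_roi_spec()) {
  stopifnot(is_mask_volume(cord_csf_mask), inherits(spec, "noise_roi_spec"))
  dil <- dilate_mask(cord_csf_mask, spec$dilation_mm)
  out <- dil$data
  out[cord_csf_mask$data == 1L] <- 0L
  d <- dim(out)
  k <- spec$edge_trim_voxels
  if (k > 0) {
    xs <- c(seq_len(min(k, d[1])), seq.int(max(d[1] - k + 1, 1), d[1]))
    ys <- c(seq_len(min(k, d[2])), seq.int(max(d[2] - k + 1, 1), d[2]))
    out[unique(xs), , ] <- 0L
    out[, unique(ys), ] <- 0L
  }
  if (sum(out) == 0)
    stop("noise ROI is empty on every slice", call. = FALSE)
  mask_volume(out, cord_csf_mask$voxel_size_mm)
}
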