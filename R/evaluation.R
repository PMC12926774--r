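#' Temporal signal-to-noise ratio of model residuals
#'
#' Adds the functional mean back to the model residuals and computes
#' tSNR = mean / standard deviation per voxel (sample standard deviation,
#' n - 1 denominator). Voxels with zero residual variance are flagged and
#' excluded from summaries rather than given a value.
#'
#' @param glm A [fit_glm()] result.
#' @param mean_map 3D array of functional means (e.g. `apply(v$data, 1:3,
#'   mean)`), or a [volume_series()] from which it is computed.
#' @return An object of class `tsnr_map` with per-voxel `tsnr`, `mean`,
#'   `resid_sd`, `coords`, and logical `flagged`.
#' @export
tsnr <- function(glm, mean_map) {
  stopifnot(inherits(glm, "glm_result"))
  if (is_volume_series(mean_map)) mean_map <- apply(mean_map$data, 1:3, mean)
  check_same_grid(dim(mean_map), glm$dims, "mean map")
  mu <- mean_map[glm$coords]
  series <- glm$residuals + rep(mu, each = glm$t_len)
  m <- colMeans(series)
  s <- apply(series, 2, stats::sd)
  flagged <- s == 0
  vals <- ifelse(flagged, NA_real_, m / s)
  structure(list(tsnr = vals, mean = m, resid_sd = s, flagged = flagged,
                 coords = glm$coords, dims = glm$dims),
            class = "tsnr_map")
}

#' @export
print.tsnr_map <- function(x, ...) {
  ok <- !x$flagged
  cat(sprintf("<tsnr_map> %d voxels (%d flagged); mean tSNR = %.2f\n",
              length(x$tsnr), sum(x$flagged), mean(x$tsnr[ok])))
  invisible(x)
}

#' Spatial Spearman correlation between two statistic maps
#'
#' Rank correlation over in-mask voxels, with average ranks on ties.
#' Used to compare where two nuisance-regressor sets (recording-based vs.
#' data-driven) explain variance.
#'
#' @param map_a,map_b 3D arrays on the same grid (NA allowed outside the
#'   computed region).
#' @param mask A [mask_volume()] selecting the voxels to compare.
#' @return Spearman's rho.
#' @export
spatial_spearman <- function(map_a, map_b, mask) {
  stopifnot(is_mask_volume(mask))
  check_same_grid(dim(map_a), dim(mask$data), "map A")
  check_same_grid(dim(map_b), dim(mask$data), "map B")
  sel <- mask$data == 1L & is.finite(map_a) & is.finite(map_b)
  a <- map_a[sel]
  b <- map_b[sel]
  if (length(a) < 3)
    stop("need at least 3 in-mask voxels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant map; Spearman correlation undefined", call. = FALSE)
  stats::cor(rank(a), rank(b), method = "pearson")
}

#' Dice similarity coefficient between two masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks
#' are empty.
#'
#' @param mask_a,mask_b [mask_volume()]s on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(is_mask_volume(mask_a), is_mask_volume(mask_b))
  check_same_grid(dim(mask_a$data), dim(mask_b$data), "mask B")
  na <- sum(mask_a$data)
  nb <- sum(mask_b$data)
  if (na + nb == 0) return(1)
  2 * sum(mask_a$data & mask_b$data) / (na + nb)
}

#' Activation-change counts between two significance masks
#'
#' Counts, within an ROI, the voxels newly active under the comparison
#' model (`now_active`), no longer active (`no_longer_active`), and active
#' under both (`both`), relative to a base model's significance mask.
#'
#' @param base_mask,other_mask Binary significance [mask_volume()]s.
#' @param roi ROI [mask_volume()] restricting the counts.
#' @return A list of integer counts.
#' @export
activation_change <- function(base_mask, other_mask, roi) {
  stopifnot(is_mask_volume(base_mask), is_mask_volume(other_mask),
            is_mask_volume(roi))
  check_same_grid(dim(base_mask$data), dim(other_mask$data), "comparison mask")
  check_same_grid(dim(base_mask$data), dim(roi$data), "ROI")
  b <- base_mask$data == 1L & roi$data == 1L
  o <- other_mask$data == 1L & roi$data == 1L
  list(now_active = sum(o & !b),
       no_longer_active = sum(b & !o),
       both = sum(b & o))
}

HORN_NAMES <- c("left_ventral", "left_dorsal", "right_ventral", "right_dorsal")

#' Slice-wise seed connectivity between gray-matter horn ROIs
#'
#' For each slice, computes the 4 x 4 Pearson correlation matrix between
#' the mean timeseries of the left-ventral, left-dorsal, right-ventral and
#' right-dorsal horn ROIs (full correlation) and Fisher r-to-z transforms
#' it (|r| clipped at 1 - 1e-7 to keep z finite). Pair classes are averaged
#' across slices: V-V (LV-RV), D-D (LD-RD), V-D within hemicord (LV-LD,
#' RV-RD), and V-D between hemicords (LV-RD, RV-LD). Slices missing any
#' horn are skipped and reported.
#'
#' @param v A [volume_series()] (typically model residuals).
#' @param horn_masks Named list of 4 [mask_volume()]s: `left_ventral`,
#'   `left_dorsal`, `right_ventral`, `right_dorsal`.
#' @param slices Optional subset of slices.
#' @return An object of class `connectivity_result`: per-slice `r` and `z`
#'   matrices, slice-averaged pair-class summary tibble, `skipped_slices`.
#' @export
seed_connectivity <- function(v, horn_masks, slices = NULL) {
  stopifnot(is_volume_series(v))
  if (!all(HORN_NAMES %in% names(horn_masks)))
    stop("`horn_masks` must contain: ", paste(HORN_NAMES, collapse = ", "),
         call. = FALSE)
  for (nm in HORN_NAMES)
    check_same_grid(dim(v$data)[1:3], dim(horn_masks[[nm]]$data), nm)
  if (is.null(slices)) slices <- seq_len(n_slices(v))
  per_slice_r <- list()
  per_slice_z <- list()
  skipped <- integer()
  for (z in slices) {
    means <- matrix(NA_real_, n_timepoints(v), 4,
                    dimnames = list(NULL, HORN_NAMES))
    ok <- TRUE
    for (h in HORN_NAMES) {
      idx <- slice_voxels(horn_masks[[h]]$data, z)
      if (nrow(idx) == 0) { ok <- FALSE; break }
      acc <- 0
      for (i in seq_len(nrow(idx)))
        acc <- acc + v$data[idx[i, 1], idx[i, 2], z, ]
      means[, h] <- acc / nrow(idx)
    }
    if (!ok || any(apply(means, 2, stats::sd) == 0)) {
      skipped <- c(skipped, z)
      next
    }
    r <- stats::cor(means)
    per_slice_r[[as.character(z)]] <- r
    per_slice_z[[as.character(z)]] <- fisher_z(r)
  }
  if (length(per_slice_r) == 0)
    stop("every slice was missing at least one horn ROI", call. = FALSE)
  pair_class <- function(zmat) c(
    vv = zmat["left_ventral", "right_ventral"],
    dd = zmat["left_dorsal", "right_dorsal"],
    vd_within = mean(c(zmat["left_ventral", "left_dorsal"],
                       zmat["right_ventral", "right_dorsal"])),
    vd_between = mean(c(zmat["left_ventral", "right_dorsal"],
                        zmat["right_ventral", "left_dorsal"])))
  per_class <- t(vapply(per_slice_z, pair_class, numeric(4)))
  summary <- tibble::tibble(
    pair_class = c("V-V", "D-D", "V-D Within", "V-D Between"),
    mean_z = unname(colMeans(per_class)),
    n_slices = nrow(per_class))
  structure(list(r = per_slice_r, z = per_slice_z, summary = summary,
                 skipped_slices = skipped),
            class = "connectivity_result")
}

fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %d slices (%d skipped)\n",
              length(x$r), length(x$skipped_slices)))
  print(x$summary)
  invisible(x)
}

#' Plot slice-averaged connectivity by pair class
#' @param object A [seed_connectivity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_result <- function(object, ...) {
  df <- object$summary
  df$pair_class <- factor(df$pair_class, levels = df$pair_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_class, y = .data$mean_z)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean Fisher z (across slices)")
}
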