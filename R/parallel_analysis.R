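#' Sample one surrogate slice matrix from a surrogate set
#'
#' For each voxel independently, one of its surrogates is drawn uniformly
#' (with replacement across matrices); column order is preserved, so the
#' sampled matrix is grid-compatible with the template slice matrix.
#'
#' @param s A [build_surrogate_set()] result.
#' @param draw_seed Integer seed for the draw.
#' @return A [slice_matrix()].
#' @export
sample_surrogate_matrix <- function(s, draw_seed) {
  stopifnot(inherits(s, "surrogate_set"))
  d <- dim(s$surrogates)
  v_len <- d[3]
  pick <- with_local_seed(draw_seed,
                          sample.int(s$n_per_voxel, v_len, replace = TRUE))
  vals <- matrix(0, d[1], v_len)
  for (v in seq_len(v_len)) vals[, v] <- s$surrogates[, pick[v], v]
  slice_matrix(vals, s$voxel_coords, s$slice_index)
}

#' Component-retention cutoff from template vs. surrogate eigencurves
#'
#' Implements the scree-curve intersection: the cutoff is the number of
#' leading components whose template eigenvalue strictly exceeds the mean
#' surrogate eigenvalue, stopping at the first violation — i.e., the last
#' template component explaining more variance than surrogate (chance-level)
#' components do. Crossings beyond the first are ignored.
#'
#' @param template_eigs Descending template eigenvalues.
#' @param surrogate_mean_eigs Mean surrogate eigenvalues (same length).
#' @return Integer cutoff in `[0, N]`.
#' @export
slice_cutoff <- function(template_eigs, surrogate_mean_eigs) {
  if (length(template_eigs) != length(surrogate_mean_eigs))
    stop("eigenvalue curves have different lengths", call. = FALSE)
  above <- template_eigs > surrogate_mean_eigs
  if (!above[1]) return(0L)
  viol <- which(!above)
  if (length(viol) == 0) return(length(template_eigs))
  as.integer(viol[1] - 1L)
}

#' @keywords internal
#' Scree curves + cutoff for one slice.
scree_curves <- function(template_eigs, surrogate_mean_eigs, n_matrices,
                         slice_index) {
  structure(list(template_eigs = template_eigs,
                 surrogate_mean_eigs = surrogate_mean_eigs,
                 n_matrices = as.integer(n_matrices),
                 cutoff = slice_cutoff(template_eigs, surrogate_mean_eigs),
                 slice_index = as.integer(slice_index)),
            class = "scree_curves")
}

#' @export
print.scree_curves <- function(x, ...) {
  cat(sprintf("<scree_curves> slice %d: cutoff %d of %d components (%d surrogate matrices)\n",
              x$slice_index, x$cutoff, length(x$template_eigs), x$n_matrices))
  invisible(x)
}

#' Parallel analysis for component retention
#'
#' Decides how many principal components to retain per slice by comparing
#' the template eigenvalue curve to the mean eigenvalue curve over
#' `n_matrices` surrogate matrices, each assembled by sampling one IAAFT
#' surrogate per voxel. Per run, the median cutoff across slices (rounded
#' half-up) is reported. Slices with fewer than 2 usable noise-ROI voxels
#' are skipped; it is an error if every slice is skipped.
#'
#' @param v A [volume_series()].
#' @param roi The noise-ROI [mask_volume()].
#' @param n_per_voxel Surrogates per voxel (default 50).
#' @param n_matrices Surrogate matrices per slice (default 500).
#' @param truncate_to Optional number of initial volumes to analyze (puts
#'   runs of different lengths on a common footing); `NULL` for no
#'   truncation.
#' @param base_seed Integer seed; all surrogate generation and matrix
#'   sampling derive deterministic substreams from it.
#' @param slices Optional subset of slice indices to analyze.
#' @param max_iter Maximum IAAFT iterations (default 500).
#' @return An object of class `parallel_analysis_result` with `per_slice`
#'   (list of `scree_curves`), `cutoffs` (named integer vector),
#'   `median_cutoff`, `truncated_to`, `skipped_slices`.
#' @export
run_parallel_analysis <- function(v, roi, n_per_voxel = 50L,
                                  n_matrices = 500L, truncate_to = NULL,
                                  base_seed = 1L, slices = NULL,
                                  max_iter = 500L) {
  stopifnot(is_volume_series(v), is_mask_volume(roi))
  if (!is.null(truncate_to)) v <- truncate_volume(v, truncate_to)
  if (is.null(slices)) slices <- seq_len(n_slices(v))
  per_slice <- list()
  skipped <- integer()
  for (z in slices) {
    m <- tryCatch(extract_slice_matrix(v, roi, z), error = function(e) NULL)
    if (is.null(m)) { skipped <- c(skipped, z); next }
    per_slice[[as.character(z)]] <- parallel_analysis_slice(
      m, n_per_voxel = n_per_voxel, n_matrices = n_matrices,
      base_seed = base_seed, max_iter = max_iter)
  }
  if (length(per_slice) == 0)
    stop("noise ROI is unusable on every requested slice", call. = FALSE)
  cutoffs <- vapply(per_slice, function(s) s$cutoff, integer(1))
  structure(list(per_slice = per_slice,
                 cutoffs = cutoffs,
                 median_cutoff = round_half_up(stats::median(cutoffs)),
                 truncated_to = if (is.null(truncate_to)) NULL
                                else as.integer(truncate_to),
                 skipped_slices = skipped),
            class = "parallel_analysis_result")
}

# covariance eigenvalues of a T x V matrix without the full SVD; agrees
# with slice_pca()$eigenvalues to numerical precision
slice_eigs <- function(x) {
  t_len <- nrow(x)
  xc <- x - rep(colMeans(x), each = t_len)
  ev <- eigen(tcrossprod(xc), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev[seq_len(min(t_len - 1L, ncol(x)))], 0) / (t_len - 1L)
}

# one slice: template PCA + n_matrices surrogate PCAs -> scree curves
parallel_analysis_slice <- function(m, n_per_voxel, n_matrices, base_seed,
                                    max_iter = 500L) {
  tpl_eigs <- slice_eigs(m$values)
  sset <- build_surrogate_set(m, n_per_voxel = n_per_voxel,
                              base_seed = base_seed, max_iter = max_iter)
  n <- length(tpl_eigs)
  acc <- numeric(n)
  for (j in seq_len(n_matrices)) {
    seed_j <- substream_seed(base_seed, m$slice_index, 999983L, j)
    sm <- sample_surrogate_matrix(sset, seed_j)
    acc <- acc + slice_eigs(sm$values)[seq_len(n)]
  }
  scree_curves(tpl_eigs, acc / n_matrices, n_matrices, m$slice_index)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' @export
print.parallel_analysis_result <- function(x, ...) {
  cat(sprintf("<parallel_analysis_result> %d slices; per-slice cutoffs: %s\n",
              length(x$per_slice), paste(x$cutoffs, collapse = ", ")))
  cat(sprintf("  median cutoff: %d%s\n", x$median_cutoff,
              if (!is.null(x$truncated_to))
                sprintf(" (analyzed on first %d volumes)", x$truncated_to)
              else ""))
  invisible(x)
}

#' Tidy per-slice parallel-analysis summary
#' @param pa A [run_parallel_analysis()] result.
#' @return A tibble with one row per slice: `slice`, `cutoff`,
#'   `n_components`, `n_matrices`.
#' @export
pa_summary <- function(pa) {
  stopifnot(inherits(pa, "parallel_analysis_result"))
  tibble::tibble(
    slice = as.integer(names(pa$per_slice)),
    cutoff = unname(pa$cutoffs),
    n_components = vapply(pa$per_slice,
                          function(s) length(s$template_eigs), integer(1),
                          USE.NAMES = FALSE),
    n_matrices = vapply(pa$per_slice, function(s) s$n_matrices, integer(1),
                        USE.NAMES = FALSE)
  )
}

#' Scree plot for one slice of a parallel analysis
#'
#' Plots the template and mean-surrogate eigenvalue curves with the
#' retained-component cutoff marked at their intersection.
#'
#' @param object A `scree_curves` object (one element of
#'   `parallel_analysis_result$per_slice`).
#' @param n_show Number of leading components to display (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scree_curves <- function(object, n_show = 40L, ...) {
  n <- min(n_show, length(object$template_eigs))
  df <- tibble::tibble(
    component = rep(seq_len(n), 2),
    eigenvalue = c(object$template_eigs[seq_len(n)],
                   object$surrogate_mean_eigs[seq_len(n)]),
    curve = rep(c("template", "surrogate mean"), each = n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$cutoff + 0.5, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Slice %d scree: cutoff %d components",
                      object$slice_index, object$cutoff),
      x = "component", y = "eigenvalue", colour = NULL)
}
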