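#' High-pass filter by discrete-cosine projection
#'
#' Projects out a discrete cosine basis spanning all periods longer than
#' `cutoff_s` seconds (plus the constant term). The same operator must be
#' applied to the data and to every regressor so that filtering and model
#' fitting commute; [fit_glm()] does this internally. The size of the
#' removed basis is attached as attribute `"filter_dof"` and later
#' subtracted from the residual degrees of freedom.
#'
#' @param x Numeric vector (length T), T x V matrix, or
#'   [regressor_table()].
#' @param tr_s Sampling interval (TR) in seconds.
#' @param cutoff_s High-pass cutoff period in seconds (default 100).
#' @return Filtered object of the same shape, with attribute `filter_dof`.
#' @export
highpass_filter <- function(x, tr_s, cutoff_s = 100) {
  if (cutoff_s <= 2 * tr_s)
    stop("`cutoff_s` must exceed twice the sampling interval", call. = FALSE)
  if (inherits(x, "regressor_table")) {
    vals <- highpass_filter(as.matrix(as.data.frame(x)), tr_s, cutoff_s)
    out <- regressor_table(as.data.frame(vals), regressor_groups(x))
    attr(out, "filter_dof") <- attr(vals, "filter_dof")
    return(out)
  }
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  t_len <- nrow(xm)
  b <- dct_basis(t_len, tr_s, cutoff_s)
  if (ncol(b) >= t_len)
    stop("high-pass basis spans the whole series; cutoff too small for T",
         call. = FALSE)
  # columns of the DCT-II basis (with the constant) are orthogonal
  coef <- crossprod(b, xm) / colSums(b^2)
  out <- xm - b %*% coef
  if (vec_in) out <- drop(out)
  attr(out, "filter_dof") <- ncol(b)
  out
}

# constant + cosines with period >= cutoff_s: k = 1..floor(2*T*tr/cutoff)
dct_basis <- function(t_len, tr_s, cutoff_s) {
  k_max <- floor(2 * t_len * tr_s / cutoff_s)
  tt <- seq_len(t_len) - 0.5
  cols <- c(list(rep(1, t_len)),
            lapply(seq_len(k_max), function(k) cos(pi * k * tt / t_len)))
  do.call(cbind, cols)
}

#' Voxel-wise general linear model within a mask
#'
#' Fits each in-mask voxel's timeseries against the design by ordinary
#' least squares after applying the same discrete-cosine high-pass filter
#' to the data and the regressors. Designs may be slice-wise (one
#' [assemble_design()] result per slice, as RETROICOR / CSF / PCA
#' regressors are) or shared across slices. An optional first-order
#' autoregressive prewhitening refit is available; it estimates the lag-1
#' residual autocorrelation per voxel and is an approximation, not a
#' replication of locally regularized prewhitening.
#'
#' @param v A [volume_series()].
#' @param design A `design_matrix`, or a list of them (one per slice).
#' @param mask Analysis [mask_volume()] (e.g. the spinal cord mask).
#' @param prewhiten `"none"` (default) or `"ar1"`.
#' @param hp_cutoff_s High-pass cutoff in seconds (default 100); `NULL`
#'   disables filtering (an intercept-only constant is still projected
#'   out so that designs with demeaned columns stay full rank).
#' @return An object of class `glm_result`.
#' @export
fit_glm <- function(v, design, mask, prewhiten = c("none", "ar1"),
                    hp_cutoff_s = 100) {
  prewhiten <- match.arg(prewhiten)
  stopifnot(is_volume_series(v), is_mask_volume(mask))
  check_same_grid(dim(v$data)[1:3], dim(mask$data), "analysis mask")
  if (sum(mask$data) == 0) stop("analysis mask is empty", call. = FALSE)
  d <- dim(v$data)
  t_len <- d[4]
  slice_designs <- normalize_designs(design, d[3])
  filt <- function(x) {
    if (is.null(hp_cutoff_s)) {
      out <- sweep(as.matrix(x), 2, colMeans(as.matrix(x)), "-")
      attr(out, "filter_dof") <- 1L
      out
    } else highpass_filter(as.matrix(x), v$tr_s, hp_cutoff_s)
  }
  coords <- NULL; betas <- NULL; resid <- NULL; yf_all <- NULL
  rss <- numeric(); slice_of <- integer()
  slice_fit <- list()
  filter_dof <- NA_integer_
  col_names <- NULL; col_groups <- NULL
  for (z in seq_len(d[3])) {
    idx <- slice_voxels(mask$data, z)
    if (nrow(idx) == 0) next
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    des <- slice_designs[[z]]
    if (is.null(des))
      stop(sprintf("no design supplied for slice %d", z), call. = FALSE)
    tbl <- des$regressors
    if (nrow(tbl) != t_len)
      stop("design length does not match the number of volumes",
           call. = FALSE)
    if (is.null(col_names)) {
      col_names <- names(tbl)
      col_groups <- regressor_groups(tbl)
    } else if (!identical(names(tbl), col_names)) {
      stop("slice designs must share the same column structure",
           call. = FALSE)
    }
    y <- matrix(0, t_len, nrow(idx))
    for (i in seq_len(nrow(idx)))
      y[, i] <- v$data[idx[i, 1], idx[i, 2], z, ]
    yf <- filt(y)
    xf <- filt(as.matrix(as.data.frame(tbl)))
    filter_dof <- attr(yf, "filter_dof")
    qrx <- qr(xf)
    if (qrx$rank < ncol(xf))
      warning(sprintf("design is rank deficient on slice %d (rank %d of %d)",
                      z, qrx$rank, ncol(xf)))
    bet <- qr.coef(qrx, yf)
    bet[is.na(bet)] <- 0
    res <- yf - xf %*% bet
    coords <- rbind(coords, cbind(idx, z))
    betas <- cbind(betas, bet)
    resid <- cbind(resid, res)
    yf_all <- cbind(yf_all, yf)
    rss <- c(rss, colSums(res^2))
    slice_of <- c(slice_of, rep.int(z, nrow(idx)))
    slice_fit[[as.character(z)]] <- list(x = xf, rank = qrx$rank, qr = qrx)
  }
  if (is.null(coords)) stop("analysis mask is empty", call. = FALSE)
  if (prewhiten == "ar1") {
    for (i in seq_len(nrow(coords))) {
      z <- slice_of[i]
      xf <- slice_fit[[as.character(z)]]$x
      e <- resid[, i]
      rho <- sum(e[-1] * e[-t_len]) / sum(e^2)
      rho <- max(min(rho, 0.99), -0.99)
      wy <- ar1_whiten(yf_all[, i], rho)
      wx <- apply(xf, 2, ar1_whiten, rho = rho)
      qrw <- qr(wx)
      bet <- qr.coef(qrw, wy)
      bet[is.na(bet)] <- 0
      res <- wy - wx %*% bet
      betas[, i] <- bet
      resid[, i] <- res
      rss[i] <- sum(res^2)
    }
  }
  ranks <- vapply(slice_fit, function(s) s$rank, integer(1))
  structure(list(
    coords = unname(coords),
    betas = betas,
    residuals = resid,
    rss = rss,
    y_filtered = yf_all,
    slice_of = slice_of,
    slice_fit = slice_fit,
    col_names = col_names,
    col_groups = col_groups,
    filter_dof = as.integer(filter_dof),
    ranks = ranks,
    residual_dof = as.integer(t_len - (max(ranks) + filter_dof)),
    t_len = t_len,
    dims = d[1:3],
    tr_s = v$tr_s,
    prewhiten = prewhiten,
    model_kind = slice_designs[[which(!vapply(slice_designs, is.null,
                                              TRUE))[1]]]$model_kind,
    voxel_size_mm = v$voxel_size_mm
  ), class = "glm_result")
}

normalize_designs <- function(design, nz) {
  if (is_design_matrix(design)) return(rep(list(design), nz))
  if (is.list(design)) {
    if (length(design) != nz)
      stop("design list must have one entry per slice", call. = FALSE)
    return(design)
  }
  stop("`design` must be a design_matrix or a list of them", call. = FALSE)
}

ar1_whiten <- function(x, rho) {
  n <- length(x)
  c(x[1] * sqrt(1 - rho^2), x[-1] - rho * x[-n])
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %s model: %d voxels, %d regressors, residual dof %d\n",
              x$model_kind, nrow(x$coords), length(x$col_names),
              x$residual_dof))
  invisible(x)
}

#' Nested F-test between a full and a reduced voxel-wise model
#'
#' Tests whether the full model's extra regressors explain additional
#' variance: `F = ((rss_r - rss_f) / df_num) / (rss_f / df_den)` per voxel,
#' with `df_num` the rank added by the extra columns and `df_den` the full
#' model's residual degrees of freedom. Both fits must share the mask and
#' the filtering.
#'
#' @param full,reduced [fit_glm()] results with the reduced design's
#'   columns a strict subset of the full design's.
#' @return An object of class `f_test_result` with per-voxel `F`, `p`, `z`,
#'   and `df_num`, `df_den`.
#' @export
nested_f_test <- function(full, reduced) {
  stopifnot(inherits(full, "glm_result"), inherits(reduced, "glm_result"))
  if (!identical(full$coords, reduced$coords))
    stop("full and reduced fits cover different voxels", call. = FALSE)
  if (!identical(full$filter_dof, reduced$filter_dof))
    stop("full and reduced fits used different filtering", call. = FALSE)
  if (!all(reduced$col_names %in% full$col_names))
    stop("designs are not nested", call. = FALSE)
  if (length(setdiff(full$col_names, reduced$col_names)) == 0)
    stop("designs are identical; nested F-test undefined", call. = FALSE)
  df_num <- max(full$ranks) - max(reduced$ranks)
  if (df_num <= 0)
    stop("full design adds no rank over the reduced design", call. = FALSE)
  df_den <- full$residual_dof
  f <- ((reduced$rss - full$rss) / df_num) / (full$rss / df_den)
  f <- pmax(f, 0)
  f_test_result(f, df_num, df_den, full)
}

f_test_result <- function(f, df_num, df_den, glm) {
  logp <- stats::pf(f, df_num, df_den, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  structure(list(F = f,
                 p = exp(logp),
                 z = z,
                 df_num = as.integer(df_num),
                 df_den = as.integer(df_den),
                 coords = glm$coords,
                 dims = glm$dims,
                 voxel_size_mm = glm$voxel_size_mm),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("<f_test_result> F(%d, %d) over %d voxels; median F = %.3f\n",
              x$df_num, x$df_den, length(x$F), stats::median(x$F)))
  invisible(x)
}

#' Omnibus F-test for a whole regressor group
#'
#' Jointly tests that an entire group of regressors (e.g. all RETROICOR
#' columns of the base model, or all PCA columns of the SpinalCompCor
#' model) explains no variance. Equivalent to the nested test against the
#' model with that group removed; implemented by refitting the reduced
#' model on the stored filtered data.
#'
#' @param glm A [fit_glm()] result.
#' @param group Group name (`"task"`, `"motion"`, `"csf"`, `"retro"`,
#'   `"pca"`).
#' @return An `f_test_result`.
#' @export
omnibus_f_test <- function(glm, group) {
  stopifnot(inherits(glm, "glm_result"))
  in_group <- glm$col_groups == group
  if (!any(in_group))
    stop(sprintf("group '%s' is empty in this design", group), call. = FALSE)
  rss_r <- numeric(length(glm$rss))
  rank_r <- integer()
  for (z in names(glm$slice_fit)) {
    sel <- glm$slice_of == as.integer(z)
    xf <- glm$slice_fit[[z]]$x[, !in_group, drop = FALSE]
    y <- glm$y_filtered[, sel, drop = FALSE]
    if (ncol(xf) == 0) {
      rss_r[sel] <- colSums(y^2)
      rank_r <- c(rank_r, 0L)
    } else {
      qrx <- qr(xf)
      res <- qr.resid(qrx, y)
      rss_r[sel] <- colSums(res^2)
      rank_r <- c(rank_r, qrx$rank)
    }
  }
  df_num <- max(glm$ranks) - max(rank_r)
  if (df_num <= 0)
    stop(sprintf("group '%s' contributes no rank after filtering", group),
         call. = FALSE)
  f <- ((rss_r - glm$rss) / df_num) / (glm$rss / glm$residual_dof)
  f_test_result(pmax(f, 0), df_num, glm$residual_dof, glm)
}

#' Significant-voxel proportion and median F inside an ROI
#'
#' @param ft An `f_test_result`.
#' @param roi A [mask_volume()] overlapping the tested voxels.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return A list with `proportion` (fraction of ROI voxels with
#'   `p < alpha`), `median_f`, and `n_voxels`.
#' @export
significant_proportion <- function(ft, roi, alpha = 0.05) {
  stopifnot(inherits(ft, "f_test_result"), is_mask_volume(roi))
  check_same_grid(ft$dims, dim(roi$data), "ROI")
  inside <- roi$data[ft$coords] == 1L
  if (!any(inside))
    stop("ROI does not overlap the tested voxels", call. = FALSE)
  list(proportion = mean(ft$p[inside] < alpha),
       median_f = stats::median(ft$F[inside]),
       n_voxels = sum(inside))
}

#' Expand per-voxel statistics into 3D maps
#'
#' @param ft An `f_test_result`.
#' @param what `"F"`, `"p"`, or `"z"`.
#' @return A 3D array with `NA` outside the tested voxels.
#' @export
stat_map <- function(ft, what = c("F", "p", "z")) {
  what <- match.arg(what)
  out <- array(NA_real_, ft$dims)
  out[ft$coords] <- ft[[what]]
  out
}
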