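#' Detect peaks in a physiological trace
#'
#' Local maxima exceeding the trace's rolling median, with a refractory
#' period: no two reported peaks are closer than `min_interval_s` (when two
#' candidates conflict the larger is kept). Suitable for pulse-oximeter
#' beats (refractory ~0.4 s) and respiratory-belt cycles (~1.5 s).
#'
#' @param trace A [physio_trace()].
#' @param min_interval_s Minimum separation between peaks in seconds.
#' @return Strictly increasing numeric vector of peak times (seconds,
#'   acquisition-aligned). Empty, with a warning, if no peaks are found.
#' @export
detect_peaks <- function(trace, min_interval_s) {
  stopifnot(inherits(trace, "physio_trace"))
  x <- trace$samples
  n <- length(x)
  if (n / trace$fs_hz <= 2 * min_interval_s)
    stop("trace shorter than twice the refractory period", call. = FALSE)
  # rolling median over ~4 refractory periods as an adaptive baseline
  w <- max(3L, round(4 * min_interval_s * trace$fs_hz))
  if (w %% 2 == 0) w <- w + 1L
  base <- stats::runmed(x, min(w, if (n %% 2 == 0) n - 1 else n))
  cand <- which(diff(sign(diff(x))) < 0) + 1L  # strict local maxima
  cand <- cand[x[cand] > base[cand]]
  if (length(cand) == 0) {
    warning("no peaks found")
    return(numeric())
  }
  # refractory pruning: greedily keep larger peaks
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- numeric()
  min_gap <- min_interval_s * trace$fs_hz
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  idx <- sort(cand[keep])
  trace$t0_s + (idx - 1) / trace$fs_hz
}

#' Cardiac phase at arbitrary sample times
#'
#' The cardiac phase at time t is the elapsed fraction of the current
#' beat-to-beat interval scaled to `[0, 2*pi)`:
#' `phi(t) = 2*pi * (t - t_prev_peak) / (t_next_peak - t_prev_peak)`.
#' Samples before the first (after the last) peak extrapolate using the
#' first (last) interval's period.
#'
#' @param peak_times Strictly increasing beat times (>= 2).
#' @param sample_times Times at which to evaluate the phase.
#' @return Numeric vector of phases in `[0, 2*pi)`.
#' @export
cardiac_phase <- function(peak_times, sample_times) {
  if (length(peak_times) < 2)
    stop("need at least 2 peaks to define cardiac phase", call. = FALSE)
  if (any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  np <- length(peak_times)
  phi <- numeric(length(sample_times))
  for (i in seq_along(sample_times)) {
    t <- sample_times[i]
    if (t < peak_times[1]) {
      p <- peak_times[2] - peak_times[1]
      phi[i] <- (2 * pi * (t - peak_times[1]) / p) %% (2 * pi)
    } else if (t >= peak_times[np]) {
      p <- peak_times[np] - peak_times[np - 1]
      phi[i] <- (2 * pi * (t - peak_times[np]) / p) %% (2 * pi)
    } else {
      k <- findInterval(t, peak_times)
      p <- peak_times[k + 1] - peak_times[k]
      phi[i] <- 2 * pi * (t - peak_times[k]) / p
    }
  }
  phi <- phi %% (2 * pi)
  phi[2 * pi - phi < 1e-9] <- 0  # guard the wrap boundary at exact peaks
  phi
}

#' Respiratory phase at arbitrary sample times
#'
#' Amplitude-histogram-equalized respiratory phase, signed by the belt
#' derivative: `phi(t) = pi * H(b(t)) * sign(db/dt)`, where `H` is the
#' cumulative histogram fraction of the belt amplitude over the whole
#' recording (computed with `n_bins` bins). Values lie in `[-pi, pi]`;
#' inhalation (rising belt) gives positive phase.
#'
#' @param belt A respiratory [physio_trace()].
#' @param sample_times Times at which to evaluate the phase.
#' @param n_bins Number of amplitude histogram bins (default 100).
#' @return Numeric vector of phases in `[-pi, pi]`.
#' @export
respiratory_phase <- function(belt, sample_times, n_bins = 100L) {
  stopifnot(inherits(belt, "physio_trace"))
  x <- belt$samples
  if (stats::sd(x) == 0)
    stop("respiratory belt trace is constant", call. = FALSE)
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  cumfrac <- cumsum(counts) / sum(counts)
  # light smoothing of the derivative to stabilize the sign near extrema
  k <- max(3L, round(belt$fs_hz / 4))
  if (k %% 2 == 0) k <- k + 1L
  xs <- stats::filter(x, rep(1 / k, k), sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  deriv <- c(diff(xs), 0)
  tt <- physio_times(belt)
  idx <- pmin(pmax(round((sample_times - belt$t0_s) * belt$fs_hz) + 1, 1),
              length(x))
  if (any(sample_times < tt[1] - 1 / belt$fs_hz) ||
      any(sample_times > tt[length(tt)] + 1 / belt$fs_hz))
    warning("some sample times fall outside the belt recording")
  b <- x[idx]
  bin <- pmin(pmax(findInterval(b, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  sgn <- sign(deriv[idx])
  sgn[sgn == 0] <- 1
  pi * cumfrac[bin] * sgn
}

#' RETROICOR Fourier regressors from cardiac and respiratory phases
#'
#' Expands the slice-wise cardiac and respiratory phases into low-order
#' Fourier terms: for each order `k = 1..M`, columns `cos(k*phi_c)`,
#' `sin(k*phi_c)`, `cos(k*phi_r)`, `sin(k*phi_r)` — 2M cardiac + 2M
#' respiratory = 4M columns (16 at the default order 4: 8 cardiac and 8
#' respiratory).
#'
#' @param phi_c Cardiac phase per volume (numeric vector of length T).
#' @param phi_r Respiratory phase per volume (length T).
#' @param order Fourier expansion order M (default 4).
#' @return A [regressor_table()] with `4 * order` columns, group `"retro"`.
#' @export
retroicor_regressors <- function(phi_c, phi_r, order = 4L) {
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (length(phi_c) != length(phi_r))
    stop("phase vectors must have equal length", call. = FALSE)
  if (any(!is.finite(phi_c)) || any(!is.finite(phi_r)))
    stop("phases must be finite", call. = FALSE)
  cols <- list()
  for (k in seq_len(order)) {
    cols[[paste0("card_cos", k)]] <- cos(k * phi_c)
    cols[[paste0("card_sin", k)]] <- sin(k * phi_c)
  }
  for (k in seq_len(order)) {
    cols[[paste0("resp_cos", k)]] <- cos(k * phi_r)
    cols[[paste0("resp_sin", k)]] <- sin(k * phi_r)
  }
  regressor_table(cols, "retro")
}

#' Slice-wise RETROICOR regressors for a volume series
#'
#' Evaluates cardiac and respiratory phases at each slice's acquisition
#' times (`volume_onset + slice_times_s[slice]`) and expands them into
#' Fourier regressors, giving genuinely slice-wise columns.
#'
#' @param v A [volume_series()].
#' @param pulse,belt [physio_trace()] recordings spanning the acquisition.
#' @param order Fourier order (default 4).
#' @param min_interval_s Length-2 vector of refractory periods in seconds
#'   for cardiac and respiratory peak detection (defaults 0.4 and 1.5).
#' @return A list (one [regressor_table()] per slice).
#' @export
slicewise_retroicor <- function(v, pulse, belt, order = 4L,
                                min_interval_s = c(0.4, 1.5)) {
  stopifnot(is_volume_series(v))
  beats <- detect_peaks(pulse, min_interval_s[1])
  if (length(beats) < 2) stop("fewer than 2 cardiac peaks", call. = FALSE)
  t_vol <- (seq_len(n_timepoints(v)) - 1) * v$tr_s
  lapply(seq_len(n_slices(v)), function(z) {
    tt <- t_vol + v$slice_times_s[z]
    retroicor_regressors(cardiac_phase(beats, tt),
                         respiratory_phase(belt, tt), order = order)
  })
}

#' Cerebrospinal-fluid nuisance regressor for one slice
#'
#' Ranks the slice's CSF voxels by temporal variance and averages the
#' timeseries of the top `ceil(top_fraction * count)` voxels into a single
#' regressor (group `"csf"`). Variance is computed on the input series,
#' before any filtering; the result is invariant to voxel ordering.
#'
#' @param v A [volume_series()].
#' @param csf_mask CSF [mask_volume()].
#' @param slice_index 1-based slice index.
#' @param top_fraction Fraction of highest-variance voxels to average
#'   (default 0.2).
#' @return A [regressor_table()] with one column `csf`.
#' @export
csf_regressor <- function(v, csf_mask, slice_index, top_fraction = 0.2) {
  stopifnot(is_volume_series(v), is_mask_volume(csf_mask))
  check_same_grid(dim(v$data)[1:3], dim(csf_mask$data), "CSF mask")
  idx <- slice_voxels(csf_mask$data, slice_index)
  if (nrow(idx) == 0)
    stop(sprintf("no CSF voxels on slice %d", slice_index), call. = FALSE)
  t_len <- n_timepoints(v)
  series <- vapply(seq_len(nrow(idx)), function(i)
    v$data[idx[i, 1], idx[i, 2], slice_index, ], numeric(t_len))
  series <- matrix(series, nrow = t_len)
  vars <- apply(series, 2, stats::var)
  n_top <- ceiling(top_fraction * nrow(idx))
  top <- order(vars, decreasing = TRUE)[seq_len(n_top)]
  regressor_table(list(csf = rowMeans(series[, top, drop = FALSE])), "csf")
}

#' Assemble a Base / Extended / SpinalCompCor design matrix
#'
#' The three model kinds are:
#' * `base`: task + motion + CSF + RETROICOR (no PCA components),
#' * `extended`: base + PCA components,
#' * `spinalcompcor`: task + motion + CSF + PCA (no recording-derived
#'   RETROICOR columns).
#'
#' All nuisance columns are demeaned at assembly; the nuisance count
#' excludes task columns.
#'
#' @param task,motion,csf,retro,pca [regressor_table()]s of common length
#'   (any of them may be empty where the model kind allows).
#' @param model_kind `"base"`, `"extended"`, or `"spinalcompcor"`.
#' @param slice_index Optional slice index carried along for slice-wise
#'   designs.
#' @return An object of class `design_matrix` with fields `regressors`,
#'   `model_kind`, `slice_index`, and `nuisance_count`.
#' @export
assemble_design <- function(task = regressor_table(), motion, csf, retro,
                            pca = regressor_table(),
                            model_kind = c("base", "extended", "spinalcompcor"),
                            slice_index = NA_integer_) {
  model_kind <- match.arg(model_kind)
  if (model_kind %in% c("extended", "spinalcompcor") && ncol(pca) == 0)
    stop(sprintf("model '%s' requires at least one PCA column", model_kind),
         call. = FALSE)
  if (model_kind %in% c("base", "extended") && ncol(retro) == 0)
    stop(sprintf("model '%s' requires RETROICOR columns", model_kind),
         call. = FALSE)
  parts <- switch(model_kind,
    base          = list(task, motion, csf, retro),
    extended      = list(task, motion, csf, retro, pca),
    spinalcompcor = list(task, motion, csf, pca))
  tbl <- do.call(bind_regressors, parts)
  groups <- regressor_groups(tbl)
  # demean nuisance columns (everything except task)
  for (nm in names(tbl)[groups != "task"]) tbl[[nm]] <- tbl[[nm]] - mean(tbl[[nm]])
  structure(list(regressors = tbl,
                 model_kind = model_kind,
                 slice_index = as.integer(slice_index),
                 nuisance_count = sum(groups != "task")),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  g <- regressor_groups(x$regressors)
  cat(sprintf("<design_matrix> %s model: %d task + %d nuisance regressors\n",
              x$model_kind, sum(g == "task"), x$nuisance_count))
  cat("  nuisance groups:",
      paste(sprintf("%s=%d", names(table(g[g != "task"])),
                    table(g[g != "task"])), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname assemble_design
#' @param x Object to test.
#' @export
is_design_matrix <- function(x) inherits(x, "design_matrix")
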