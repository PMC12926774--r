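#' @keywords internal
#' Deterministic substream seed from a base seed and integer ids.
#' Keeps every derived seed in [0, 2^31 - 2] so set.seed() is safe.
substream_seed <- function(base_seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (v in c(base_seed, ...)) h <- (h * 1000003 + (v %% m)) %% m
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' IAAFT surrogate of a single timeseries
#'
#' Iterative amplitude adjusted Fourier transform: starting from a random
#' permutation of the template, each iteration (a) replaces the current
#' surrogate's Fourier amplitudes with the template's while keeping the
#' current phases (the zero-frequency term is copied from the template), then
#' (b) rank-order remaps the result onto the template's sorted values.
#' Iteration stops when the rank ordering no longer changes, or after
#' `max_iter` iterations. Because the final step is always the amplitude
#' adjustment, the surrogate's value multiset equals the template's exactly,
#' while its power spectrum approximates the template's with randomized
#' phases — so surrogates are, on average, uncorrelated with the template.
#'
#' @param x Numeric template timeseries, length >= 8.
#' @param seed Integer seed for the initial permutation.
#' @param max_iter Maximum iterations (default 500).
#' @return List with `surrogate` (numeric, same length as `x`) and
#'   `iterations` (integer; 0 for a constant input, which is returned
#'   unchanged).
#' @export
iaaft_surrogate <- function(x, seed, max_iter = 500L) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("template must have length >= 8", call. = FALSE)
  if (any(!is.finite(x))) stop("template must be finite", call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(surrogate = x, iterations = 0L))
  init <- with_local_seed(seed, x[sample.int(length(x))])
  res <- iaaft_batch(matrix(x), matrix(init), max_iter = max_iter)
  list(surrogate = res$surrogates[, 1], iterations = res$iterations[1])
}

# per-column order() of a matrix in one stable radix pass
col_order <- function(m) {
  t_len <- nrow(m)
  n <- ncol(m)
  if (n == 1L)
    return(matrix(order(m[, 1], method = "radix"), t_len, 1L))
  g <- order(rep.int(seq_len(n), rep.int(t_len, n)), as.vector(m),
             method = "radix")
  matrix(as.integer(g - rep.int((seq_len(n) - 1L) * t_len,
                                rep.int(t_len, n))),
         t_len, n)
}

# Batched IAAFT: `templates` and `inits` are T x C matrices; each column is
# iterated independently (columns that converge drop out of the active set).
# Column-wise identical to iaaft_surrogate() on the same init.
iaaft_batch <- function(templates, inits, max_iter = 500L) {
  t_len <- nrow(templates)
  n_col <- ncol(templates)
  f_tpl <- stats::mvfft(templates)
  amp_a <- Mod(f_tpl)
  dc_a <- f_tpl[1, ]
  o <- col_order(templates)
  off_all <- rep.int((seq_len(n_col) - 1L) * t_len, rep.int(t_len, n_col))
  st_a <- templates
  st_a[] <- templates[as.vector(o) + off_all]  # column-sorted templates

  out <- inits
  iterations <- rep(max_iter, n_col)
  act <- seq_len(n_col)  # global ids of still-iterating columns
  s <- inits
  prev <- matrix(0L, t_len, n_col)

  for (it in seq_len(max_iter)) {
    f_cur <- stats::mvfft(s)
    mod <- Mod(f_cur)
    unit <- f_cur / mod
    bad <- mod == 0
    if (any(bad)) unit[bad] <- 1 + 0i
    y <- unit * amp_a
    y[1, ] <- dc_a
    sp <- Re(stats::mvfft(y, inverse = TRUE)) / t_len
    ord <- col_order(sp)
    na <- ncol(sp)
    off <- rep.int((seq_len(na) - 1L) * t_len, rep.int(t_len, na))
    # rank-order remap onto the template's sorted values (stable ties)
    s_new <- sp
    s_new[as.vector(ord) + off] <- st_a
    conv <- colSums(ord == prev) == t_len
    if (any(conv)) {
      iterations[act[conv]] <- it
      out[, act[conv]] <- s_new[, conv]
      keep <- !conv
      act <- act[keep]
      if (length(act) == 0L) { s <- NULL; break }
      s <- s_new[, keep, drop = FALSE]
      amp_a <- amp_a[, keep, drop = FALSE]
      dc_a <- dc_a[keep]
      st_a <- st_a[, keep, drop = FALSE]
      prev <- ord[, keep, drop = FALSE]
    } else {
      s <- s_new
      prev <- ord
    }
  }
  if (!is.null(s) && length(act) > 0L) out[, act] <- s
  list(surrogates = out, iterations = as.integer(iterations))
}

#' Generate a set of IAAFT surrogates for every voxel of a slice matrix
#'
#' Produces `n_per_voxel` surrogates per voxel. Each surrogate's initial
#' permutation is seeded from a deterministic substream derived from
#' `(base_seed, slice, voxel, replicate)`, so the set is reproducible
#' bit-exactly regardless of execution order.
#'
#' @param m A [slice_matrix()].
#' @param n_per_voxel Surrogates per voxel (default 50).
#' @param base_seed Integer base seed.
#' @param max_iter Maximum IAAFT iterations per surrogate (default 500).
#' @return An object of class `surrogate_set`: `surrogates` is a
#'   T x n_per_voxel x V array, `iterations` an n_per_voxel x V matrix.
#' @export
build_surrogate_set <- function(m, n_per_voxel = 50L, base_seed,
                                max_iter = 500L) {
  stopifnot(inherits(m, "slice_matrix"))
  n_per_voxel <- as.integer(n_per_voxel)
  if (n_per_voxel < 1L) stop("`n_per_voxel` must be >= 1", call. = FALSE)
  t_len <- nrow(m$values)
  v_len <- ncol(m$values)
  templates <- m$values[, rep(seq_len(v_len), each = n_per_voxel),
                        drop = FALSE]
  inits <- templates
  col <- 0L
  for (v in seq_len(v_len)) {
    xv <- m$values[, v]
    for (j in seq_len(n_per_voxel)) {
      col <- col + 1L
      seed <- substream_seed(base_seed, m$slice_index, v, j)
      inits[, col] <- with_local_seed(seed, xv[sample.int(t_len)])
    }
  }
  res <- iaaft_batch(templates, inits, max_iter = max_iter)
  structure(list(
    surrogates = array(res$surrogates, dim = c(t_len, n_per_voxel, v_len)),
    iterations = matrix(res$iterations, nrow = n_per_voxel),
    n_per_voxel = n_per_voxel,
    base_seed = base_seed,
    slice_index = m$slice_index,
    voxel_coords = m$voxel_coords
  ), class = "surrogate_set")
}

#' Amplitude-spectrum preservation error of surrogates
#'
#' Quantifies how well surrogates preserve the template's Fourier amplitude
#' spectrum. Amplitudes are taken over the non-zero-frequency half spectrum
#' (the zero-frequency term is preserved exactly by construction). Two
#' summaries are returned: `per_surrogate`, the RMS (2-norm) relative error
#' of each surrogate's amplitude spectrum against the template's, and
#' `of_mean`, the relative error of the surrogate-set mean amplitude
#' spectrum — the quantity the parallel analysis effectively relies on,
#' since surrogate eigencurves enter only through means. The per-surrogate
#' error has an intrinsic floor set by the algorithm's fixed point
#' (typically 2-3% at T = 160); averaging across a surrogate set removes
#' its random part.
#'
#' @param template Numeric template timeseries.
#' @param surrogates Matrix with one surrogate per column (or a single
#'   vector).
#' @return List with `per_surrogate` (numeric vector) and `of_mean`
#'   (scalar).
#' @export
surrogate_spectrum_error <- function(template, surrogates) {
  if (is.null(dim(surrogates))) surrogates <- matrix(surrogates, ncol = 1)
  t_len <- length(template)
  stopifnot(nrow(surrogates) == t_len)
  half <- 2:(floor(t_len / 2) + 1)
  a <- Mod(stats::fft(template))[half]
  amps <- Mod(stats::mvfft(surrogates))[half, , drop = FALSE]
  per <- apply(amps, 2, function(b) sqrt(sum((b - a)^2) / sum(a^2)))
  list(per_surrogate = per,
       of_mean = sqrt(sum((rowMeans(amps) - a)^2) / sum(a^2)))
}

#' @export
print.surrogate_set <- function(x, ...) {
  d <- dim(x$surrogates)
  cat(sprintf(
    "<surrogate_set> slice %d: %d surrogates x %d voxels (T = %d)\n",
    x$slice_index, d[2], d[3], d[1]))
  invisible(x)
}
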