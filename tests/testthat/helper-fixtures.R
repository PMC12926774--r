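# Shared fixtures, built in code. Phantoms are cached per-session because
# several test files reuse the same configurations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# deterministic AR(1) series without touching the global RNG stream
ar1_series <- function(n, phi = 0.5, seed = 1L, sd = 1) {
  e <- local_rnorm(n + 50, seed)
  x <- numeric(n + 50)
  for (t in 2:(n + 50)) x[t] <- phi * x[t - 1] + e[t]
  sd * x[(length(x) - n + 1):length(x)]
}

local_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n)
}

local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runif(n)
}

# small phantom with 5 strong planted components confined to the noise
# region (clear-separation regime used for recovery tests); ~300 noise
# voxels per slice
recovery_phantom_config <- function(seed, k = 5L) {
  phantom_config(nx = 26L, ny = 26L, n_slices = 1L, n_volumes = 160L,
                 k_components = k, component_amplitude = 8,
                 cardiac_amplitude = 0, resp_amplitude = 0,
                 drift_amplitude = 0, thermal_sd = 1, seed = seed)
}

# pure-thermal-noise phantom (no planted structure of any kind)
null_phantom_config <- function(seed) {
  phantom_config(nx = 26L, ny = 26L, n_slices = 1L, n_volumes = 160L,
                 k_components = 0L, cardiac_amplitude = 0,
                 resp_amplitude = 0, drift_amplitude = 0,
                 thermal_sd = 1, seed = seed)
}

# default-conditions phantom shared across modeling/evaluation tests
default_phantom <- function() {
  cached("default_phantom", function() {
    simulate_phantom(phantom_config(n_slices = 3L, seed = 1L))
  })
}

# fraction of an injected slice-wise cardiac component's variance that a
# fitted model removed from each contaminated voxel's residuals
acceptance_cardiac_removal <- function(fit, ph, cfg) {
  t_len <- cfg$n_volumes
  removed <- numeric(0)
  for (i in seq_len(nrow(fit$coords))) {
    co <- fit$coords[i, ]
    w <- ph$truth$cardiac_weight_map[co[1], co[2]]
    if (w == 0) next
    phi <- cardiac_phase(ph$truth$beat_times,
                         (0:(t_len - 1)) * cfg$tr_s +
                           ph$truth$slice_times_s[co[3]])
    injected <- cfg$cardiac_amplitude * w *
      spinalcompcor:::cardiac_waveform(phi)
    b <- stats::cov(fit$residuals[, i], injected) / stats::var(injected)
    removed <- c(removed, 1 - b^2)
  }
  removed
}

# design-matrix fixture: motion + csf + retro (+ optionally pca) tables of
# length t_len with reproducible contents
fixture_tables <- function(t_len, n_motion = 2L, retro_order = 4L,
                           k_pca = 0L, seed = 7L) {
  vals <- local_rnorm(t_len * (n_motion + 1L + k_pca), seed)
  i <- 0L
  take <- function() {
    i <<- i + 1L
    vals[((i - 1L) * t_len + 1L):(i * t_len)]
  }
  motion <- regressor_table(
    stats::setNames(replicate(n_motion, take(), simplify = FALSE),
                    paste0("moco_", seq_len(n_motion))), "motion")
  csf <- regressor_table(list(csf = take()), "csf")
  tt <- seq_len(t_len)
  retro <- retroicor_regressors(2 * pi * (tt %% 17) / 17,
                                pi * sin(tt / 9), order = retro_order)
  pca <- if (k_pca > 0)
    regressor_table(stats::setNames(
      replicate(k_pca, take(), simplify = FALSE),
      paste0("PC", seq_len(k_pca))), "pca")
  else regressor_table()
  list(motion = motion, csf = csf, retro = retro, pca = pca)
}
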