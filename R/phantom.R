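#' Configuration for the synthetic cord phantom
#'
#' Describes a concentric cord / CSF / surrounding-tissue geometry with the
#' noise structure typical of cervical spinal cord fMRI: quasi-periodic
#' cardiac pulsation concentrated in CSF and vessel voxels, slower
#' respiratory fluctuation in muscle, low-order drift, optional bulk-motion
#' spikes, white thermal noise, optional planted PCA-recoverable noise
#' components, an optional block task confined to ventral-horn voxels, and
#' optional shared horn timecourses for connectivity tests. Defaults give a
#' 32 x 32 x 6 x 160 grid at 1 x 1 x 3 mm and TR 2 s — the sampling regime
#' in which ~1 Hz cardiac noise aliases, as it does in TR = 2 s in vivo
#' acquisitions.
#'
#' @param nx,ny,n_slices,n_volumes Grid dimensions.
#' @param voxel_size_mm Voxel sizes (mm).
#' @param tr_s Repetition interval (s).
#' @param cord_radius_mm,csf_outer_radius_mm Concentric radii (cord < CSF).
#' @param k_components Number of planted PCA-recoverable noise components.
#' @param component_amplitude Per-component amplitude (signal s.d. units at
#'   full map weight).
#' @param cardiac_rate_hz,cardiac_amplitude Cardiac pulsation rate and
#'   amplitude (CSF/vessel support).
#' @param resp_rate_hz,resp_amplitude Respiratory rate and amplitude
#'   (muscle support).
#' @param rate_jitter_frac Fractional cycle-to-cycle jitter of cardiac and
#'   respiratory intervals.
#' @param drift_amplitude Amplitude of the quadratic drift.
#' @param motion_spike_volumes Integer volumes at which bulk-motion spikes
#'   occur (edge-weighted offsets); empty for none.
#' @param motion_spike_amplitude Spike amplitude.
#' @param thermal_sd Thermal (white) noise standard deviation.
#' @param task_amplitude Task response amplitude (0 = resting state).
#' @param task_block_s Task block length in seconds (on/off alternation).
#' @param task_correlated_noise_amplitude Amplitude of a task-correlated
#'   noise component placed in the noise ROI.
#' @param horn_shared_r Named numeric of target horn-mean correlations to
#'   plant, e.g. `c(vv = 0.6)`; classes `vv`, `dd`, `vd_within`,
#'   `vd_between`.
#' @param baseline Baseline image intensity.
#' @param seed Integer seed; the phantom is fully reproducible from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(nx = 32L, ny = 32L, n_slices = 6L,
                           n_volumes = 160L,
                           voxel_size_mm = c(1, 1, 3), tr_s = 2,
                           cord_radius_mm = 4, csf_outer_radius_mm = 6,
                           k_components = 0L, component_amplitude = 8,
                           cardiac_rate_hz = 1.0, cardiac_amplitude = 4,
                           resp_rate_hz = 0.25, resp_amplitude = 2,
                           rate_jitter_frac = 0.03,
                           drift_amplitude = 2,
                           motion_spike_volumes = integer(),
                           motion_spike_amplitude = 0,
                           thermal_sd = 1,
                           task_amplitude = 0, task_block_s = 30,
                           task_correlated_noise_amplitude = 0,
                           horn_shared_r = c(),
                           baseline = 1000,
                           seed = 1L) {
  if (cord_radius_mm >= csf_outer_radius_mm)
    stop("cord radius must be smaller than the CSF outer radius",
         call. = FALSE)
  if (k_components < 0) stop("`k_components` must be >= 0", call. = FALSE)
  amps <- c(component_amplitude, cardiac_amplitude, resp_amplitude,
            drift_amplitude, motion_spike_amplitude, thermal_sd,
            task_amplitude, task_correlated_noise_amplitude)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %dx%dx%d grid, %d volumes, TR %g s, K = %d, seed %d\n",
              x$nx, x$ny, x$n_slices, x$n_volumes, x$tr_s, x$k_components,
              x$seed))
  invisible(x)
}

# jittered event times covering [0, duration]; deterministic from seed
jittered_event_times <- function(duration_s, rate_hz, jitter_frac, seed) {
  period <- 1 / rate_hz
  n <- ceiling((duration_s + 4 * period) * rate_hz) + 2L
  gaps <- with_local_seed(seed,
    period * pmax(1 + jitter_frac * stats::rnorm(n), 0.2))
  times <- cumsum(c(period / 2, gaps[-1]))
  times[times <= duration_s + 2 * period]
}

# unit-variance pulsatile waveform of a phase in [0, 2*pi): sharp systolic
# peak (low-order Fourier shape, so order-4 RETROICOR can model it exactly)
cardiac_waveform <- function(phi) {
  w <- 1.0 * cos(phi) + 0.5 * cos(2 * phi) + 0.25 * cos(3 * phi) +
    0.12 * cos(4 * phi) + 0.3 * sin(2 * phi) + 0.1 * sin(3 * phi)
  w / sqrt(1.0^2 / 2 + 0.5^2 / 2 + 0.25^2 / 2 + 0.12^2 / 2 +
             0.3^2 / 2 + 0.1^2 / 2)
}

#' Simulate a ground-truth-known cord phantom
#'
#' Builds the 4D series `baseline + planted components + cardiac +
#' respiratory + drift + motion spikes + task + thermal noise` on a
#' concentric cord/CSF/tissue geometry, together with every mask the
#' pipeline needs and a truth record for parameter-recovery tests
#' (component timecourses and maps, true task betas, beat/breath times, and
#' per-voxel noise-free variance for bookkeeping checks).
#'
#' @param cfg A [phantom_config()].
#' @return A list with elements `func` ([volume_series()]), `masks` (named
#'   list of [mask_volume()]s: `cord`, `csf`, `cord_csf`, `vessels`,
#'   `muscle`, `noise_region`, `horns`), and `truth`.
#' @export
simulate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$n_slices; t_len <- cfg$n_volumes
  vs <- cfg$voxel_size_mm
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- ((1:nx) - cx) * vs[1]
  ys <- ((1:ny) - cy) * vs[2]
  r2 <- outer(xs^2, ys^2, "+")
  cord2d <- r2 <= cfg$cord_radius_mm^2
  csf2d <- r2 > cfg$cord_radius_mm^2 & r2 <= cfg$csf_outer_radius_mm^2
  vessel2d <- matrix(FALSE, nx, ny)
  for (vx in c(-9, 9)) {
    vr2 <- outer((xs - vx)^2, ys^2, "+")
    vessel2d <- vessel2d | (vr2 <= 1.5^2)
  }
  vessel2d <- vessel2d & !cord2d & !csf2d
  muscle2d <- !cord2d & !csf2d & !vessel2d
  trim <- 3L
  border2d <- matrix(FALSE, nx, ny)
  border2d[c(seq_len(trim), seq.int(nx - trim + 1, nx)), ] <- TRUE
  border2d[, c(seq_len(trim), seq.int(ny - trim + 1, ny))] <- TRUE
  noise2d <- (muscle2d | vessel2d) & !border2d

  rep3d <- function(m2d) array(rep(m2d, nz), c(nx, ny, nz))
  masks <- list(
    cord = mask_volume(rep3d(cord2d) * 1L, vs),
    csf = mask_volume(rep3d(csf2d) * 1L, vs),
    cord_csf = mask_volume(rep3d(cord2d | csf2d) * 1L, vs),
    vessels = mask_volume(rep3d(vessel2d) * 1L, vs),
    muscle = mask_volume(rep3d(muscle2d) * 1L, vs),
    noise_region = mask_volume(rep3d(noise2d) * 1L, vs)
  )
  # gray-matter horn seeds: 2x2 voxel blocks ~2 mm from center;
  # left = -x, right = +x, ventral = -y, dorsal = +y
  horn_block <- function(dx, dy) {
    m <- matrix(FALSE, nx, ny)
    hx <- round(cx + dx / vs[1]) + 0:1
    hy <- round(cy + dy / vs[2]) + 0:1
    m[hx, hy] <- TRUE
    m & cord2d
  }
  horn2d <- list(left_ventral = horn_block(-2.2, -2.2),
                 left_dorsal = horn_block(-2.2, 1.2),
                 right_ventral = horn_block(1.2, -2.2),
                 right_dorsal = horn_block(1.2, 1.2))
  masks$horns <- lapply(horn2d, function(m) mask_volume(rep3d(m) * 1L, vs))

  duration_s <- t_len * cfg$tr_s
  slice_times <- (seq_len(nz) - 1) / nz * cfg$tr_s
  t_vol <- (seq_len(t_len) - 1) * cfg$tr_s

  sig <- array(cfg$baseline, c(nx, ny, nz, t_len))
  truth <- list(config = cfg, slice_times_s = slice_times)

  # planted PCA-recoverable components: orthogonal unit-variance
  # timecourses on random muscle-voxel supports inside the noise region
  k <- cfg$k_components
  if (k > 0 && cfg$component_amplitude > 0) {
    raw <- with_local_seed(substream_seed(cfg$seed, 101L), {
      m <- matrix(stats::rnorm(t_len * k), t_len, k)
      apply(m, 2, function(col) as.numeric(stats::filter(
        col, rep(1 / 3, 3), circular = TRUE)))
    })
    raw <- sweep(matrix(raw, t_len, k), 2, colMeans(matrix(raw, t_len, k)))
    q <- qr.Q(qr(raw))
    tcs <- apply(q, 2, function(col) col / stats::sd(col))
    tcs <- matrix(tcs, t_len, k)
    region_idx <- which(noise2d)
    maps <- vector("list", k)
    for (j in seq_len(k)) {
      if (length(region_idx) < 2)
        stop("noise region too small to support planted components",
             call. = FALSE)
      sub <- with_local_seed(substream_seed(cfg$seed, 102L, j), {
        n_sup <- min(length(region_idx),
                     max(10L, round(0.4 * length(region_idx))))
        picked <- region_idx[sample.int(length(region_idx), n_sup)]
        w <- stats::runif(n_sup, 0.7, 1)
        list(picked = picked, w = w)
      })
      map2d <- matrix(0, nx, ny)
      map2d[sub$picked] <- sub$w
      maps[[j]] <- map2d
      add <- cfg$component_amplitude *
        outer(map2d, tcs[, j])  # nx x ny x T
      for (z in seq_len(nz)) sig[, , z, ] <- sig[, , z, ] + add
    }
    truth$component_timecourses <- tcs
    truth$component_maps <- maps
  } else {
    truth$component_timecourses <- matrix(0, t_len, 0)
    truth$component_maps <- list()
  }

  # cardiac: slice-time-resolved Fourier waveform of the true cardiac phase
  beat_times <- jittered_event_times(duration_s, cfg$cardiac_rate_hz,
                                     cfg$rate_jitter_frac,
                                     substream_seed(cfg$seed, 201L))
  truth$beat_times <- beat_times
  if (cfg$cardiac_amplitude > 0) {
    card2d <- (csf2d | vessel2d) * 1
    wmap <- with_local_seed(substream_seed(cfg$seed, 202L),
      card2d * matrix(stats::runif(nx * ny, 0.7, 1), nx, ny))
    for (z in seq_len(nz)) {
      phi <- cardiac_phase(beat_times, t_vol + slice_times[z])
      tc <- cardiac_waveform(phi)
      sig[, , z, ] <- sig[, , z, ] +
        cfg$cardiac_amplitude * outer(wmap, tc)
    }
    truth$cardiac_weight_map <- wmap
  }

  # respiratory: slower quasi-periodic oscillation in muscle
  breath_onsets <- jittered_event_times(duration_s, cfg$resp_rate_hz,
                                        cfg$rate_jitter_frac,
                                        substream_seed(cfg$seed, 301L))
  truth$breath_onsets <- breath_onsets
  if (cfg$resp_amplitude > 0) {
    wmap <- with_local_seed(substream_seed(cfg$seed, 302L),
      muscle2d * matrix(stats::runif(nx * ny, 0.5, 1), nx, ny))
    for (z in seq_len(nz)) {
      phi <- cardiac_phase(breath_onsets, t_vol + slice_times[z])
      tc <- -cos(phi)
      sig[, , z, ] <- sig[, , z, ] + cfg$resp_amplitude * outer(wmap, tc)
    }
  }

  # quadratic drift, global support
  if (cfg$drift_amplitude > 0) {
    tt <- (t_vol - mean(t_vol)) / (duration_s / 2)
    drift <- cfg$drift_amplitude * (0.7 * tt + 0.5 * (tt^2 - mean(tt^2)))
    sig <- sig + rep(drift, each = nx * ny * nz)
    truth$drift <- drift
  }

  # bulk-motion spikes: edge-weighted global offsets at scheduled volumes
  if (length(cfg$motion_spike_volumes) > 0 &&
      cfg$motion_spike_amplitude > 0) {
    base2d <- cfg$baseline * (1 + 0.2 * cord2d - 0.1 * csf2d)
    gx <- rbind(diff(base2d), 0)
    gy <- cbind(t(apply(base2d, 1, function(r) c(diff(r), 0))))
    edgew <- sqrt(gx^2 + gy^2)
    if (max(edgew) > 0) edgew <- edgew / max(edgew)
    for (j in cfg$motion_spike_volumes) {
      if (j < 1 || j > t_len) stop("motion spike volume out of range",
                                   call. = FALSE)
      for (z in seq_len(nz))
        sig[, , z, j] <- sig[, , z, j] + cfg$motion_spike_amplitude * edgew
    }
    truth$motion_spike_volumes <- cfg$motion_spike_volumes
  }

  # block task confined to the ventral horns
  task_tc <- rep(0, t_len)
  beta_map <- array(0, c(nx, ny, nz))
  if (cfg$task_amplitude > 0) {
    block_len <- max(1L, round(cfg$task_block_s / cfg$tr_s))
    task_tc <- rep(rep(c(0, 1), each = block_len),
                   length.out = t_len)
    vh2d <- horn2d$left_ventral | horn2d$right_ventral
    if (!any(vh2d & cord2d)) stop("task voxels fall outside the cord",
                                  call. = FALSE)
    for (z in seq_len(nz)) {
      beta_map[, , z] <- cfg$task_amplitude * vh2d
      sig[, , z, ] <- sig[, , z, ] +
        outer(cfg$task_amplitude * vh2d, task_tc)
    }
    if (cfg$task_correlated_noise_amplitude > 0) {
      tcn2d <- with_local_seed(substream_seed(cfg$seed, 401L),
        noise2d * matrix(stats::runif(nx * ny) < 0.3, nx, ny))
      for (z in seq_len(nz))
        sig[, , z, ] <- sig[, , z, ] +
          outer(cfg$task_correlated_noise_amplitude * tcn2d, task_tc)
    }
  }
  truth$task_timecourse <- task_tc
  truth$task_beta <- beta_map

  # shared horn timecourses to plant known seed-connectivity levels
  if (length(cfg$horn_shared_r) > 0) {
    pair_map <- list(
      vv = list(c("left_ventral", "right_ventral")),
      dd = list(c("left_dorsal", "right_dorsal")),
      vd_within = list(c("left_ventral", "left_dorsal"),
                       c("right_ventral", "right_dorsal")),
      vd_between = list(c("left_ventral", "right_dorsal"),
                        c("right_ventral", "left_dorsal")))
    shared <- list()
    for (cls in names(cfg$horn_shared_r)) {
      r_target <- cfg$horn_shared_r[[cls]]
      tc <- with_local_seed(substream_seed(cfg$seed, 501L, match(cls, names(pair_map))),
                            stats::rnorm(t_len))
      tc <- (tc - mean(tc)) / stats::sd(tc)
      for (pair in pair_map[[cls]]) {
        for (h in pair) {
          nv <- sum(horn2d[[h]])
          a <- sqrt(r_target / (1 - r_target)) * cfg$thermal_sd / sqrt(nv)
          for (z in seq_len(nz))
            sig[, , z, ] <- sig[, , z, ] + outer(a * horn2d[[h]], tc)
        }
      }
      shared[[cls]] <- tc
    }
    truth$horn_shared_timecourses <- shared
  }

  # noise-free per-voxel variance for bookkeeping checks
  truth$planted_var <- apply(sig, 1:3, stats::var)
  truth$thermal_sd <- cfg$thermal_sd

  if (cfg$thermal_sd > 0) {
    noise <- with_local_seed(substream_seed(cfg$seed, 601L),
      array(stats::rnorm(length(sig), sd = cfg$thermal_sd), dim(sig)))
    sig <- sig + noise
  }

  func <- volume_series(sig, voxel_size_mm = vs, tr_s = cfg$tr_s,
                        slice_times_s = slice_times)
  list(func = func, masks = masks, truth = truth)
}

#' Simulate pulse and respiratory-belt recordings
#'
#' Generates a pulse-oximeter-like trace (Gaussian systolic bumps at
#' jittered beat times) and a respiratory-belt trace (smooth oscillation at
#' jittered breath intervals), with the ground-truth event times recorded.
#' With the same `seed` (and rates) as [simulate_phantom()], the beat times
#' match the phantom's injected cardiac timecourse exactly.
#'
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate (>= 20 Hz; default 100).
#' @param hr_bpm Heart rate in beats per minute (default 60).
#' @param rr_bpm Respiratory rate in breaths per minute (default 15).
#' @param jitter_frac Fractional interval jitter (default 0.03).
#' @param seed Integer seed.
#' @return A list with `pulse` and `resp` ([physio_trace()]s), `beat_times`,
#'   and `breath_peak_times`.
#' @export
simulate_physio <- function(duration_s, fs_hz = 100, hr_bpm = 60,
                            rr_bpm = 15, jitter_frac = 0.03, seed = 1L) {
  if (fs_hz < 20) stop("`fs_hz` must be >= 20 Hz", call. = FALSE)
  tt <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  beat_times <- jittered_event_times(duration_s, hr_bpm / 60, jitter_frac,
                                     substream_seed(seed, 201L))
  pulse <- rep(0, length(tt))
  for (b in beat_times) pulse <- pulse + exp(-(tt - b)^2 / (2 * 0.05^2))
  breath_onsets <- jittered_event_times(duration_s, rr_bpm / 60, jitter_frac,
                                        substream_seed(seed, 301L))
  phi <- cardiac_phase(breath_onsets, tt)
  belt <- -cos(phi)
  # belt peaks occur at mid-cycle (phase pi) between consecutive onsets
  inside <- breath_onsets[breath_onsets < duration_s]
  peak_times <- inside[-length(inside)] + diff(inside) / 2
  peak_times <- peak_times[peak_times < duration_s]
  list(pulse = physio_trace(pulse, fs_hz, "pulse"),
       resp = physio_trace(belt, fs_hz, "respiratory"),
       beat_times = beat_times[beat_times >= 0 & beat_times < duration_s],
       breath_peak_times = peak_times)
}
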