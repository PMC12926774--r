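test_that("peak detection finds sinusoid maxima at the period spacing", {
  fs <- 100
  period <- 1.1
  tt <- seq(0, 60, by = 1 / fs)
  tr <- physio_trace(sin(2 * pi * tt / period), fs, "pulse")
  pk <- detect_peaks(tr, min_interval_s = 0.5)
  expect_gt(length(pk), 50)
  expect_lt(max(abs(diff(pk) - period)), 1 / fs + 1e-9)

  expect_error(detect_peaks(physio_trace(rep(0, 300), 100, "pulse"), 10),
               "shorter")
  expect_warning(
    out <- detect_peaks(physio_trace(rep(1, 1000), 100, "pulse"), 0.5),
    "no peaks")
  expect_length(out, 0)
})

test_that("simulated heartbeats are recovered exactly, with no extras", {
  sim <- simulate_physio(duration_s = 120, fs_hz = 100, hr_bpm = 70,
                         jitter_frac = 0.05, seed = 21L)
  pk <- detect_peaks(sim$pulse, min_interval_s = 0.4)
  truth <- sim$beat_times
  expect_equal(length(pk), length(truth))
  expect_lt(max(abs(pk - truth)), 1 / sim$pulse$fs_hz + 1e-9)
})

test_that("cardiac phase follows the elapsed beat fraction", {
  peaks <- c(0, 1, 2.5, 3.5)
  expect_equal(cardiac_phase(peaks, 1), 0)
  expect_equal(cardiac_phase(peaks, 1.75), pi)
  # constant heart period P: phase is (2*pi*t/P) mod 2*pi
  peaks <- seq(0, 30, by = 0.8)
  tt <- seq(0.05, 29.5, by = 0.37)
  expect_equal(cardiac_phase(peaks, tt), (2 * pi * tt / 0.8) %% (2 * pi),
               tolerance = 1e-10)
  # extrapolation outside the span uses the nearest interval's rate
  expect_equal(cardiac_phase(c(1, 2, 3), 0.5), pi, tolerance = 1e-10)
  expect_equal(cardiac_phase(c(1, 2, 3), 3.25), pi / 2, tolerance = 1e-10)
  expect_error(cardiac_phase(c(1), 0.5), "2 peaks")
})

test_that("respiratory phase equalizes amplitude histogram and signs by derivative", {
  fs <- 25
  tt <- seq(0, 120, by = 1 / fs)
  belt <- physio_trace(-cos(2 * pi * tt / 4), fs, "respiratory")
  # at the global maximum (end-inspiration), |phi| is near pi
  t_max <- 2 - 1 / fs  # just before the peak: still inhaling
  phi <- respiratory_phase(belt, t_max)
  expect_gt(phi, 0.9 * pi)
  # at the global minimum the cumulative fraction is near 0
  # cumulative fraction near 0; the arcsine density of a sinusoid piles
  # mass at the extremes, so the lowest attainable |phi| is ~0.2
  phi_min <- respiratory_phase(belt, 4.0 + 1 / fs)
  expect_lt(abs(phi_min), 0.3)
  # all phases within [-pi, pi]
  phis <- respiratory_phase(belt, seq(1, 119, by = 0.5))
  expect_true(all(phis >= -pi & phis <= pi))

  # triangular wave: uniform histogram -> |phi| proportional to amplitude
  tri <- physio_trace(rep(c(seq(0, 1, length.out = 26)[-26],
                            seq(1, 0, length.out = 26)[-26]), 40),
                      fs_hz = 25, kind = "respiratory")
  st <- seq(10, 30, by = 0.11)
  phis <- respiratory_phase(tri, st, n_bins = 200)
  amp <- tri$samples[round(st * 25) + 1]
  up <- phis > 0
  expect_gt(stats::cor(abs(phis), amp), 0.98)
  expect_true(any(up) && any(!up))
  expect_error(respiratory_phase(physio_trace(rep(1, 200) + 0, 25,
                                              "respiratory"), 1),
               "constant")
})

test_that("RETROICOR expansion has 4M columns and matches the sinusoid oracle", {
  t_len <- 150
  tr_s <- 2
  p <- 0.9  # constant heart period
  tt <- (seq_len(t_len) - 1) * tr_s
  phi_c <- (2 * pi * tt / p) %% (2 * pi)
  phi_r <- pi * sin(tt / 7)
  reg <- retroicor_regressors(phi_c, phi_r, order = 4)
  expect_equal(ncol(reg), 16)
  expect_equal(sum(startsWith(names(reg), "card")), 8)
  expect_equal(sum(startsWith(names(reg), "resp")), 8)
  expect_equal(unname(regressor_groups(reg)), rep("retro", 16))
  expect_equal(ncol(retroicor_regressors(phi_c, phi_r, order = 1)), 4)
  for (k in 1:4) {
    expect_equal(reg[[paste0("card_cos", k)]], cos(2 * pi * k * tt / p),
                 tolerance = 1e-10)
    expect_equal(reg[[paste0("card_sin", k)]], sin(2 * pi * k * tt / p),
                 tolerance = 1e-10)
  }
})

test_that("slice-wise RETROICOR evaluates phases at slice acquisition times", {
  ph <- simulate_phantom(phantom_config(nx = 12, ny = 12, n_slices = 2,
                                        n_volumes = 60, cardiac_amplitude = 0,
                                        resp_amplitude = 0, seed = 2L))
  sim <- simulate_physio(duration_s = 120, seed = 2L)
  regs <- slicewise_retroicor(ph$func, sim$pulse, sim$resp)
  expect_length(regs, 2)
  expect_equal(ncol(regs[[1]]), 16)
  expect_equal(nrow(regs[[1]]), 60)
  # different slice times give different columns
  expect_false(identical(regs[[1]]$card_cos1, regs[[2]]$card_cos1))
})

test_that("CSF regressor averages the top-variance fraction", {
  nx <- 12; ny <- 12; t_len <- 50
  arr <- array(0, c(nx, ny, 1, t_len))
  # 100-voxel CSF mask: first 100 voxels of the slice in column-major order
  csf <- array(0L, c(nx, ny, 1))
  csf[seq_len(100)] <- 1L
  sds <- seq(0.1, 10, length.out = 100)[order(local_runif(100, 13))]
  series <- matrix(local_rnorm(t_len * 100, 17), t_len, 100)
  series <- sweep(series, 2, apply(series, 2, stats::sd), "/")
  series <- sweep(series, 2, sds, "*")
  idx <- which(csf[, , 1] == 1L, arr.ind = TRUE)
  for (i in seq_len(100)) arr[idx[i, 1], idx[i, 2], 1, ] <- series[, i]
  v <- volume_series(arr, c(1, 1, 3), 2)
  reg <- csf_regressor(v, mask_volume(csf, c(1, 1, 3)), 1)
  top <- order(apply(series, 2, stats::var), decreasing = TRUE)[1:20]
  expect_equal(reg$csf, rowMeans(series[, top]), tolerance = 1e-12)

  # 5 voxels with variances (1,2,3,4,100): ceil(0.2*5) = 1 voxel
  arr5 <- array(0, c(5, 1, 1, t_len))
  for (i in 1:5) arr5[i, 1, 1, ] <- series[, i] / stats::sd(series[, i]) *
      sqrt(c(1, 2, 3, 4, 100)[i])
  m5 <- array(0L, c(5, 1, 1)); m5[, 1, 1] <- 1L
  v5 <- volume_series(arr5, c(1, 1, 3), 2)
  reg5 <- csf_regressor(v5, mask_volume(m5, c(1, 1, 3)), 1)
  expect_equal(reg5$csf, arr5[5, 1, 1, ], tolerance = 1e-12)

  # single CSF voxel: regressor equals that voxel's series
  m1 <- array(0L, c(5, 1, 1)); m1[2, 1, 1] <- 1L
  reg1 <- csf_regressor(v5, mask_volume(m1, c(1, 1, 3)), 1)
  expect_equal(reg1$csf, arr5[2, 1, 1, ], tolerance = 1e-12)

  empty <- mask_volume(array(0L, c(5, 1, 1)), c(1, 1, 3))
  expect_error(csf_regressor(v5, empty, 1), "no CSF voxels")
})

test_that("design assembly produces the three model kinds with correct counts", {
  t_len <- 120
  tabs <- fixture_tables(t_len, k_pca = 9L)
  task <- regressor_table(list(task = rep(c(0, 1), each = 10,
                                          length.out = t_len)), "task")

  base <- assemble_design(task, tabs$motion, tabs$csf, tabs$retro,
                          model_kind = "base")
  expect_equal(base$nuisance_count, 19)  # 2 motion + 1 csf + 16 retro
  expect_false("pca" %in% regressor_groups(base$regressors))

  ext <- assemble_design(task, tabs$motion, tabs$csf, tabs$retro, tabs$pca,
                         model_kind = "extended")
  expect_equal(ext$nuisance_count, 28)  # 19 + 9

  scc <- assemble_design(task, tabs$motion, tabs$csf, tabs$retro, tabs$pca,
                         model_kind = "spinalcompcor")
  expect_equal(scc$nuisance_count, 12)  # 3 + 9
  expect_false("retro" %in% regressor_groups(scc$regressors))
  expect_gt(scc$nuisance_count, 3)

  # group partition over nuisance columns is disjoint and exhaustive
  g <- regressor_groups(ext$regressors)
  expect_equal(sum(g != "task"), ext$nuisance_count)
  expect_true(all(g %in% c("task", "motion", "csf", "retro", "pca")))

  # nuisance columns are demeaned; the task column is not
  for (nm in names(ext$regressors)[g != "task"])
    expect_equal(mean(ext$regressors[[nm]]), 0, tolerance = 1e-12)
  expect_gt(mean(ext$regressors$task), 0)

  expect_error(assemble_design(task, tabs$motion, tabs$csf, tabs$retro,
                               model_kind = "extended"), "PCA")
  expect_error(assemble_design(task, tabs$motion, tabs$csf,
                               regressor_table(), tabs$pca,
                               model_kind = "base"), "RETROICOR")
})
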