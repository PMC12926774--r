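test_that("a silent phantom is constant at baseline", {
  cfg <- phantom_config(nx = 10, ny = 10, n_slices = 1, n_volumes = 20,
                        k_components = 0, cardiac_amplitude = 0,
                        resp_amplitude = 0, drift_amplitude = 0,
                        thermal_sd = 0, seed = 1)
  ph <- simulate_phantom(cfg)
  expect_equal(max(abs(ph$func$data - cfg$baseline)), 0)
})

test_that("phantom geometry is consistent and masks are disjoint where stated", {
  ph <- default_phantom()
  m <- ph$masks
  expect_equal(sum(m$cord$data & m$csf$data), 0)
  expect_equal(m$cord_csf$data, (m$cord$data | m$csf$data) * 1L,
               ignore_attr = TRUE)
  expect_equal(sum(m$noise_region$data & m$cord_csf$data), 0)
  for (h in m$horns) expect_equal(sum(h$data & !m$cord$data), 0)
  # horns pairwise disjoint
  total <- Reduce(`+`, lapply(m$horns, function(h) h$data))
  expect_lte(max(total), 1)
})

test_that("phantom is reproducible from its seed", {
  cfg <- phantom_config(nx = 18, ny = 18, n_slices = 2, n_volumes = 30,
                        k_components = 2, seed = 5)
  a <- simulate_phantom(cfg)
  b <- simulate_phantom(cfg)
  expect_identical(a$func$data, b$func$data)
  cfg2 <- cfg; cfg2$seed <- 6L
  c2 <- simulate_phantom(cfg2)
  expect_false(identical(a$func$data, c2$func$data))
})

test_that("variance bookkeeping: planted + thermal matches empirical variance", {
  ph <- default_phantom()
  t_len <- dim(ph$func$data)[4]
  emp <- apply(ph$func$data, 1:3, stats::var)
  pred <- ph$truth$planted_var + ph$truth$thermal_sd^2
  # chi-square-style bounds per voxel are loose; check in aggregate and
  # per-voxel at 6 sd of the sampling spread of a variance estimate
  ratio <- emp / pred
  expect_lt(abs(mean(ratio) - 1), 0.05)
  spread <- sqrt(2 / (t_len - 1)) * 6
  expect_gt(mean(abs(ratio - 1) < spread + 0.1), 0.99)
})

test_that("planted components produce an eigen-gap at K in the noise ROI", {
  ph <- simulate_phantom(recovery_phantom_config(seed = 9L))
  m <- extract_slice_matrix(ph$func, ph$masks$noise_region, 1)
  eigs <- slice_pca(m)$eigenvalues
  # thermal bulk edge for a T x V pure-noise matrix (Marchenko-Pastur-ish)
  bulk <- ph$truth$thermal_sd^2 * (1 + sqrt(ncol(m$values) / nrow(m$values)))^2
  expect_equal(sum(eigs > 3 * bulk), 5)
  expect_gt(eigs[5] / eigs[6], 5)
})

test_that("task beta is recovered by OLS within sampling error", {
  cfg <- phantom_config(nx = 20, ny = 20, n_slices = 1, n_volumes = 160,
                        k_components = 0, cardiac_amplitude = 0,
                        resp_amplitude = 0, drift_amplitude = 0,
                        thermal_sd = 1, task_amplitude = 0.9, seed = 4)
  ph <- simulate_phantom(cfg)
  task <- regressor_table(list(task = ph$truth$task_timecourse), "task")
  nuis <- regressor_table(list(dummy = ar1_series(160, 0.3, 2)), "motion")
  des <- assemble_design(task = task, motion = nuis,
                         csf = regressor_table(), retro = regressor_table(),
                         model_kind = "spinalcompcor",
                         pca = regressor_table(
                           list(PC1 = ar1_series(160, 0.2, 3)), "pca"))
  fit <- fit_glm(ph$func, des, ph$masks$cord, hp_cutoff_s = NULL)
  task_vox <- ph$truth$task_beta[fit$coords] > 0
  expect_gt(sum(task_vox), 0)
  bhat <- fit$betas[1, task_vox]
  tol <- 3 * cfg$thermal_sd / sqrt(sum((ph$truth$task_timecourse -
                                          mean(ph$truth$task_timecourse))^2))
  expect_true(all(abs(bhat - cfg$task_amplitude) < tol * 1.5))
  expect_lt(abs(mean(bhat) - cfg$task_amplitude), tol)
})

test_that("simulated physiology has the right beat count, spacing and determinism", {
  sim <- simulate_physio(duration_s = 300, fs_hz = 100, hr_bpm = 60,
                         jitter_frac = 0, seed = 8)
  expect_lte(abs(length(sim$beat_times) - 300), 1)
  expect_equal(max(abs(diff(sim$beat_times) - 1)), 0, tolerance = 1e-9)
  sim2 <- simulate_physio(duration_s = 300, fs_hz = 100, hr_bpm = 60,
                          jitter_frac = 0, seed = 8)
  expect_identical(sim$pulse$samples, sim2$pulse$samples)
  expect_identical(sim$resp$samples, sim2$resp$samples)

  # belt peaks are recovered by detect_peaks near the truth times
  pk <- detect_peaks(sim$resp, min_interval_s = 1.5)
  truth <- sim$breath_peak_times
  matched <- sapply(truth, function(t) min(abs(pk - t)))
  expect_lt(stats::median(matched), 0.05)
})

test_that("phantom beat times match the physio simulator under a shared seed", {
  cfg <- phantom_config(nx = 10, ny = 10, n_slices = 1, n_volumes = 40,
                        seed = 12)
  ph <- simulate_phantom(cfg)
  sim <- simulate_physio(duration_s = 40 * cfg$tr_s,
                         hr_bpm = cfg$cardiac_rate_hz * 60,
                         rr_bpm = cfg$resp_rate_hz * 60,
                         jitter_frac = cfg$rate_jitter_frac, seed = 12)
  inside <- ph$truth$beat_times[ph$truth$beat_times < 40 * cfg$tr_s]
  expect_equal(sim$beat_times, inside)
})

test_that("the Base model removes injected order-4 cardiac contamination", {
  cfg <- phantom_config(nx = 16, ny = 16, n_slices = 2, n_volumes = 160,
                        k_components = 0, cardiac_amplitude = 5,
                        resp_amplitude = 1, drift_amplitude = 1,
                        thermal_sd = 1, seed = 3)
  ph <- simulate_phantom(cfg)
  sim <- simulate_physio(duration_s = 160 * cfg$tr_s,
                         hr_bpm = cfg$cardiac_rate_hz * 60,
                         rr_bpm = cfg$resp_rate_hz * 60,
                         jitter_frac = cfg$rate_jitter_frac, seed = 3)
  retro <- slicewise_retroicor(ph$func, sim$pulse, sim$resp)
  t_len <- 160
  tabs <- fixture_tables(t_len)
  designs <- lapply(1:2, function(z)
    assemble_design(motion = tabs$motion,
                    csf = csf_regressor(ph$func, ph$masks$csf, z),
                    retro = retro[[z]], model_kind = "base",
                    slice_index = z))
  # evaluate on cardiac-contaminated voxels (CSF + vessels)
  card_mask <- ph$masks$csf
  card_mask$data <- ((ph$masks$csf$data + ph$masks$vessels$data) > 0) * 1L
  fit <- fit_glm(ph$func, designs, card_mask)

  # injected cardiac variance per voxel vs. what remains in the residuals
  removed <- numeric(nrow(fit$coords))
  for (i in seq_len(nrow(fit$coords))) {
    co <- fit$coords[i, ]
    w <- ph$truth$cardiac_weight_map[co[1], co[2]]
    if (w == 0) next
    phi <- cardiac_phase(ph$truth$beat_times,
                         (0:(t_len - 1)) * cfg$tr_s +
                           ph$truth$slice_times_s[co[3]])
    injected <- cfg$cardiac_amplitude * w *
      spinalcompcor:::cardiac_waveform(phi)
    res <- fit$residuals[, i]
    proj <- stats::lm.fit(cbind(1, injected), res)$fitted.values
    removed[i] <- 1 - stats::var(proj - mean(proj)) / stats::var(injected)
  }
  keep <- removed != 0
  expect_gt(mean(removed[keep]), 0.99)
})
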