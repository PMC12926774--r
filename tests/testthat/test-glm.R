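small_glm_volume <- function(t_len = 60, nvox = 4, seed = 5,
                             maker = NULL) {
  arr <- array(local_rnorm(2 * 2 * 1 * t_len, seed), c(2, 2, 1, t_len))
  if (!is.null(maker))
    for (i in 1:2) for (j in 1:2) arr[i, j, 1, ] <- maker((i - 1) * 2 + j)
  volume_series(arr, c(1, 1, 3), 2)
}

full_mask_2x2 <- function() mask_volume(array(1L, c(2, 2, 1)), c(1, 1, 3))

design_of <- function(cols, groups, t_len) {
  tabs <- regressor_table(cols, groups)
  structure(list(regressors = tabs, model_kind = "base", slice_index = 1L,
                 nuisance_count = sum(groups != "task")),
            class = "design_matrix")
}

fit_glm_oracle <- function(x, y) {
  stats::lm.fit(x, y)$coefficients
}

test_that("discrete-cosine high-pass removes slow and keeps fast fluctuations", {
  t_len <- 300; tr <- 2
  expect_equal(highpass_filter(rep(5, t_len), tr), rep(0, t_len),
               tolerance = 1e-10, ignore_attr = TRUE)
  tt <- (seq_len(t_len) - 1) * tr
  slow <- sin(2 * pi * tt / 200)   # 200 s period, above the 100 s cutoff
  fast <- sin(2 * pi * tt / 20)    # 20 s period, well below
  expect_lt(sum(highpass_filter(slow, tr)^2) / sum(slow^2), 0.10)
  expect_gt(sum(highpass_filter(fast, tr)^2) / sum(fast^2), 0.95)
  # matches explicit projection onto the DCT basis
  x <- local_rnorm(t_len, 31)
  b <- spinalcompcor:::dct_basis(t_len, tr, 100)
  oracle <- stats::lm.fit(b, x)$residuals
  expect_equal(highpass_filter(x, tr), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(highpass_filter(x, tr), "filter_dof"), ncol(b))
  expect_error(highpass_filter(x, tr_s = 2, cutoff_s = 3), "twice")
})

test_that("GLM fits exactly-spanned data and matches closed-form OLS", {
  t_len <- 60
  x1 <- local_rnorm(t_len, 1)
  # data built inside the design span (after filtering)
  xf <- highpass_filter(x1, 2)
  v <- small_glm_volume(t_len, maker = function(i) 3 * i * xf)
  des <- design_of(list(task = x1), "task", t_len)
  fit <- fit_glm(v, des, full_mask_2x2())
  expect_lt(max(fit$rss / colSums(fit$y_filtered^2)), 1e-16)

  # closed form: beta = cov(x, y) / var(x) for a demeaned single regressor
  v2 <- small_glm_volume(t_len, seed = 9)
  fit2 <- fit_glm(v2, des, full_mask_2x2(), hp_cutoff_s = NULL)
  for (i in seq_len(4)) {
    y <- fit2$y_filtered[, i]
    xd <- x1 - mean(x1)
    expect_equal(unname(fit2$betas[1, i]),
                 sum(xd * y) / sum(xd^2), tolerance = 1e-10)
  }

  # voxels outside the mask are absent
  m <- full_mask_2x2(); m$data[1, 1, 1] <- 0L
  fit3 <- fit_glm(v2, des, m)
  expect_equal(nrow(fit3$coords), 3)
  expect_false(any(fit3$coords[, 1] == 1 & fit3$coords[, 2] == 1))
})

test_that("filtering data+regressors equals including the filter basis as regressors", {
  t_len <- 80
  x1 <- local_rnorm(t_len, 2)
  v <- small_glm_volume(t_len, seed = 12)
  des <- design_of(list(task = x1), "task", t_len)
  fit_f <- fit_glm(v, des, full_mask_2x2(), hp_cutoff_s = 100)
  b <- spinalcompcor:::dct_basis(t_len, 2, 100)
  for (i in seq_len(4)) {
    co <- fit_glm_oracle(cbind(x1, b), v$data[fit_f$coords[i, 1],
                                              fit_f$coords[i, 2], 1, ])
    expect_equal(unname(fit_f$betas[1, i]), unname(co[1]), tolerance = 1e-8)
  }
})

test_that("nested F-test matches a hand-coded two-fit oracle", {
  # tiny 8-timepoint, 1-extra-regressor case
  t_len <- 8
  x1 <- c(1, 2, 1, 3, 2, 4, 3, 5)
  x2 <- c(0, 1, 1, 0, 1, 1, 0, 0)
  arr <- array(local_rnorm(1 * 1 * 1 * t_len, 30), c(1, 1, 1, t_len))
  v <- volume_series(arr, c(1, 1, 3), 2)
  m <- mask_volume(array(1L, c(1, 1, 1)), c(1, 1, 3))
  des_f <- design_of(list(a = x1, b = x2), c("motion", "csf"), t_len)
  des_r <- design_of(list(a = x1), "motion", t_len)
  fit_f <- fit_glm(v, des_f, m, hp_cutoff_s = NULL)
  fit_r <- fit_glm(v, des_r, m, hp_cutoff_s = NULL)
  ft <- nested_f_test(fit_f, fit_r)

  # independent two-fit oracle with lm()
  y <- arr[1, 1, 1, ]
  o_f <- stats::lm(y ~ x1 + x2)
  o_r <- stats::lm(y ~ x1)
  rss_f <- sum(residuals(o_f)^2)
  rss_r <- sum(residuals(o_r)^2)
  f_oracle <- ((rss_r - rss_f) / 1) / (rss_f / o_f$df.residual)
  expect_equal(ft$F, f_oracle, tolerance = 1e-10)
  expect_equal(ft$df_num, 1L)
  expect_equal(ft$df_den, o_f$df.residual)
  expect_equal(ft$p, stats::pf(f_oracle, 1, o_f$df.residual,
                               lower.tail = FALSE), tolerance = 1e-12)

  expect_error(nested_f_test(fit_f, fit_f), "identical")
  expect_error(nested_f_test(fit_r, fit_f), "not nested")
})

test_that("added columns orthogonal to the data give F = 0, p = 1", {
  t_len <- 40
  x1 <- local_rnorm(t_len, 3)
  v <- small_glm_volume(t_len, seed = 5)
  # orthogonalize the extra column against the data, x1, and the constant:
  # then it cannot reduce any voxel's residual sum of squares
  ymat <- matrix(aperm(v$data, c(4, 1, 2, 3)), t_len)
  extra <- qr.resid(qr(cbind(1, x1, ymat)), local_rnorm(t_len, 4))
  des_r <- design_of(list(a = x1), "motion", t_len)
  des_f <- design_of(list(a = x1, b = extra), c("motion", "csf"), t_len)
  m <- full_mask_2x2()
  fit_r <- fit_glm(v, des_r, m, hp_cutoff_s = NULL)
  fit_f <- fit_glm(v, des_f, m, hp_cutoff_s = NULL)
  ft <- nested_f_test(fit_f, fit_r)
  expect_equal(max(ft$F), 0, tolerance = 1e-8)
  expect_equal(min(ft$p), 1, tolerance = 1e-8)
})

test_that("omnibus F-test equals the nested test dropping the group", {
  t_len <- 60
  tabs <- fixture_tables(t_len, k_pca = 0L, seed = 8L)
  v <- small_glm_volume(t_len, seed = 14)
  m <- full_mask_2x2()
  des_full <- assemble_design(motion = tabs$motion, csf = tabs$csf,
                              retro = tabs$retro, model_kind = "base")
  fit_full <- fit_glm(v, des_full, m)
  omni <- omnibus_f_test(fit_full, "retro")

  g <- regressor_groups(des_full$regressors)
  keep <- g != "retro"
  des_red <- design_of(as.list(as.data.frame(des_full$regressors)[keep]),
                       g[keep], t_len)
  fit_red <- fit_glm(v, des_red, m)
  nested <- nested_f_test(fit_full, fit_red)
  expect_equal(omni$F, nested$F, tolerance = 1e-10)
  expect_equal(omni$df_num, nested$df_num)
  expect_equal(omni$df_den, nested$df_den)
  expect_error(omnibus_f_test(fit_full, "pca"), "empty")
})

test_that("RSS never increases when regressors are added", {
  t_len <- 50
  v <- small_glm_volume(t_len, seed = 22)
  m <- full_mask_2x2()
  cols <- list()
  prev_rss <- NULL
  for (k in 1:5) {
    cols[[paste0("r", k)]] <- local_rnorm(t_len, 40 + k)
    des <- design_of(cols, rep("motion", k), t_len)
    fit <- fit_glm(v, des, m)
    if (!is.null(prev_rss)) expect_true(all(fit$rss <= prev_rss + 1e-10))
    prev_rss <- fit$rss
  }
})

test_that("nested-test p-values are uniform under the null and z is monotone in F", {
  # 10,000 white-noise voxels, one extra null regressor
  t_len <- 50
  nvox <- 10000
  y <- matrix(local_rnorm(t_len * nvox, 77), t_len, nvox)
  x1 <- local_rnorm(t_len, 78)
  x2 <- local_rnorm(t_len, 79)
  q_r <- qr(cbind(1, x1))
  q_f <- qr(cbind(1, x1, x2))
  rss_r <- colSums(qr.resid(q_r, y)^2)
  rss_f <- colSums(qr.resid(q_f, y)^2)
  df_den <- t_len - 3
  f <- (rss_r - rss_f) / (rss_f / df_den)
  p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)

  ft <- spinalcompcor:::f_test_result(
    f[1:100], 1L, df_den,
    list(coords = cbind(1:100, 1L, 1L), dims = c(100, 1, 1),
         voxel_size_mm = c(1, 1, 1)))
  o <- order(ft$F)
  expect_true(all(diff(ft$z[o]) > 0))
  expect_true(all(ft$p > 0 & ft$p <= 1))
  # z transform is log-space safe for enormous F
  big <- spinalcompcor:::f_test_result(
    c(1e4, 2e4), 10L, 100L,
    list(coords = cbind(1:2, 1L, 1L), dims = c(2, 1, 1),
         voxel_size_mm = c(1, 1, 1)))
  expect_true(all(is.finite(big$z)))
  expect_gt(big$z[2], big$z[1])
})

test_that("significant_proportion summarizes an ROI", {
  t_len <- 40
  v <- small_glm_volume(t_len, seed = 50)
  m <- full_mask_2x2()
  des_r <- design_of(list(a = local_rnorm(t_len, 51)), "motion", t_len)
  des_f <- design_of(list(a = local_rnorm(t_len, 51),
                          b = local_rnorm(t_len, 52)),
                     c("motion", "csf"), t_len)
  ft <- nested_f_test(fit_glm(v, des_f, m), fit_glm(v, des_r, m))
  sp <- significant_proportion(ft, m)
  expect_true(sp$proportion >= 0 && sp$proportion <= 1)
  expect_equal(sp$n_voxels, 4)
  one <- full_mask_2x2(); one$data[] <- 0L; one$data[2, 2, 1] <- 1L
  sp1 <- significant_proportion(ft, one)
  expect_equal(sp1$median_f, ft$F[ft$coords[, 1] == 2 & ft$coords[, 2] == 2])
  off <- full_mask_2x2(); off$data[] <- 0L
  expect_error(significant_proportion(ft, off), "overlap")
})

test_that("AR(1) prewhitening runs and leaves a white-noise fit essentially unchanged", {
  t_len <- 60
  v <- small_glm_volume(t_len, seed = 61)
  des <- design_of(list(a = local_rnorm(t_len, 62)), "motion", t_len)
  m <- full_mask_2x2()
  f0 <- fit_glm(v, des, m, prewhiten = "none")
  f1 <- fit_glm(v, des, m, prewhiten = "ar1")
  expect_equal(dim(f1$betas), dim(f0$betas))
  expect_equal(unname(f1$betas[1, ]), unname(f0$betas[1, ]),
               tolerance = 0.3)
})
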