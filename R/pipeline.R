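#' Run the full denoising pipeline from one configuration
#'
#' Orchestrates noise-ROI construction, the parallel analysis, slice-wise
#' PCA regressor generation, nuisance-design assembly, voxel-wise GLMs for
#' the requested models, and the evaluation metrics, writing all outputs
#' under `out_dir` together with a JSON manifest. Every source of
#' randomness derives a named substream from the single config seed, so a
#' run is reproducible byte-for-byte.
#'
#' The configuration is a named list (or a YAML file path) with elements:
#' * `out_dir` — output directory.
#' * `seed` — integer run seed (default 1).
#' * `simulate` — list of [phantom_config()] arguments to generate inputs,
#'   or `NULL` to read `inputs`.
#' * `inputs` — paths: `func`, `cord_csf_mask`, `cord_mask`, `csf_mask`,
#'   optional `motion` (2-column TSV), `task` (TSV), `pulse`/`resp` (TSV,
#'   with `physio_fs_hz`), optional `horn_masks` (named list of 4 paths).
#' * `noise_roi` — [noise_roi_spec()] arguments (default 18 mm, trim 3).
#' * `parallel_analysis` — `n_per_voxel` (50), `n_matrices` (500),
#'   `truncate_to` (NULL), `max_iter` (500).
#' * `models` — subset of `base`, `extended`, `spinalcompcor`.
#' * `k` — `"auto"` (use the parallel-analysis median on the full,
#'   untruncated series) or an integer count of PCA regressors.
#' * `alpha` (0.05), `hp_cutoff_s` (100), `retroicor_order` (4).
#'
#' @param cfg Configuration list or YAML file path.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- apply_config_defaults(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("spinalcompcor")),
                   seed = cfg$seed, models = cfg$models, stages = character())
  # per-stage timing goes to the console log; the manifest records only the
  # stage order so that reruns with the same seed are byte-identical
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[spinalcompcor] stage %-24s %7.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  ins <- t_stage("inputs", pipeline_inputs(cfg, out_dir))
  func <- ins$func

  roi_spec <- do.call(noise_roi_spec, cfg$noise_roi)
  noise_roi <- t_stage("noise_roi", build_noise_roi(ins$cord_csf, roi_spec))
  write_mask(noise_roi, file.path(out_dir, "noise_roi.nii"))

  pa_cfg <- cfg$parallel_analysis
  pa <- t_stage("parallel_analysis", run_parallel_analysis(
    func, noise_roi, n_per_voxel = pa_cfg$n_per_voxel,
    n_matrices = pa_cfg$n_matrices, truncate_to = pa_cfg$truncate_to,
    base_seed = substream_seed(cfg$seed, 11L), max_iter = pa_cfg$max_iter))
  utils::write.table(pa_summary(pa), file.path(out_dir, "pa_cutoffs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$parallel_analysis <- list(
    per_slice_cutoffs = unname(as.list(pa$cutoffs)),
    median_cutoff = pa$median_cutoff,
    truncated_to = pa$truncated_to)

  if (identical(cfg$k, "auto")) {
    k <- if (is.null(pa_cfg$truncate_to) ||
             pa_cfg$truncate_to == n_timepoints(func)) {
      pa$median_cutoff
    } else {
      # component count for modeling comes from the full series
      pa_full <- t_stage("parallel_analysis_full", run_parallel_analysis(
        func, noise_roi, n_per_voxel = pa_cfg$n_per_voxel,
        n_matrices = pa_cfg$n_matrices, truncate_to = NULL,
        base_seed = substream_seed(cfg$seed, 12L),
        max_iter = pa_cfg$max_iter))
      pa_full$median_cutoff
    }
  } else k <- as.integer(cfg$k)
  need_pca <- any(cfg$models %in% c("extended", "spinalcompcor"))
  if (need_pca && k < 1)
    stop("parallel analysis retained no components; ",
         "extended/spinalcompcor models need k >= 1", call. = FALSE)
  manifest$k <- k

  nz <- n_slices(func)
  pcs <- t_stage("pca", lapply(seq_len(nz), function(z) {
    m <- tryCatch(extract_slice_matrix(func, noise_roi, z),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    slice_pca(m)
  }))

  designs <- t_stage("designs", {
    retro <- if (!is.null(ins$pulse))
      slicewise_retroicor(func, ins$pulse, ins$resp,
                          order = cfg$retroicor_order)
    else NULL
    out <- list()
    for (model in cfg$models) {
      out[[model]] <- lapply(seq_len(nz), function(z) {
        pca_tab <- if (need_pca && !is.null(pcs[[z]]) && k > 0)
          pc_regressors(pcs[[z]], min(k, pcs[[z]]$n_components))
        else regressor_table()
        assemble_design(
          task = ins$task, motion = ins$motion,
          csf = csf_regressor(func, ins$csf, z),
          retro = if (is.null(retro)) regressor_table() else retro[[z]],
          pca = pca_tab, model_kind = model, slice_index = z)
      })
    }
    out
  })
  for (model in cfg$models)
    write_regressors(designs[[model]][[1]]$regressors,
                     file.path(out_dir, paste0("design_", model,
                                               "_slice1.tsv")))

  fits <- t_stage("glm", lapply(designs, function(d)
    fit_glm(func, d, ins$cord, hp_cutoff_s = cfg$hp_cutoff_s)))

  mean_map <- apply(func$data, 1:3, mean)
  metrics <- list()
  sig_masks <- list()

  if (all(c("base", "extended") %in% cfg$models)) {
    ft <- nested_f_test(fits$extended, fits$base)
    for (w in c("F", "z"))
      write_volume_map(stat_map(ft, w), func,
                       file.path(out_dir, paste0("nested_", w, ".nii")))
    sp <- significant_proportion(ft, ins$cord, alpha = cfg$alpha)
    metrics$nested_extended_vs_base <- list(
      df_num = ft$df_num, df_den = ft$df_den,
      median_f = sp$median_f, significant_proportion = sp$proportion)
  }

  omni <- list()
  if ("base" %in% cfg$models && "retro" %in% fits$base$col_groups)
    omni$retro_base <- omnibus_f_test(fits$base, "retro")
  if ("spinalcompcor" %in% cfg$models)
    omni$pca_spinalcompcor <- omnibus_f_test(fits$spinalcompcor, "pca")
  for (nm in names(omni)) {
    write_volume_map(stat_map(omni[[nm]], "z"), func,
                     file.path(out_dir, paste0("omnibus_", nm, "_z.nii")))
    sig_masks[[nm]] <- binarize_mask(
      threshold_p_mask(omni[[nm]], cfg$alpha), 0.5, func$voxel_size_mm)
  }
  if (length(omni) == 2) {
    metrics$spearman_retro_vs_pca <- spatial_spearman(
      stat_map(omni$retro_base, "z"),
      stat_map(omni$pca_spinalcompcor, "z"), ins$cord)
    metrics$dice_retro_vs_pca <- dice(sig_masks[[1]], sig_masks[[2]])
    metrics$activation_change <- activation_change(
      sig_masks$retro_base, sig_masks$pca_spinalcompcor, ins$cord)
  }

  metrics$tsnr <- lapply(fits, function(fit) {
    tm <- tsnr(fit, mean_map)
    list(mean = mean(tm$tsnr[!tm$flagged]),
         median = stats::median(tm$tsnr[!tm$flagged]))
  })

  if (!is.null(ins$horns)) {
    metrics$connectivity <- lapply(fits, function(fit) {
      res_vol <- residual_volume(fit, func)
      conn <- seed_connectivity(res_vol, ins$horns)
      stats::setNames(as.list(conn$summary$mean_z), conn$summary$pair_class)
    })
  }

  manifest$metrics <- metrics
  manifest$outputs <- manifest_checksums(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

apply_config_defaults <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$models <- cfg$models %||% c("base", "extended", "spinalcompcor")
  bad <- setdiff(cfg$models, c("base", "extended", "spinalcompcor"))
  if (length(bad) > 0 || length(cfg$models) == 0)
    stop("`models` must be a non-empty subset of base/extended/spinalcompcor",
         call. = FALSE)
  cfg$noise_roi <- cfg$noise_roi %||% list()
  pa <- cfg$parallel_analysis %||% list()
  pa$n_per_voxel <- pa$n_per_voxel %||% 50L
  pa$n_matrices <- pa$n_matrices %||% 500L
  pa$max_iter <- pa$max_iter %||% 500L
  cfg$parallel_analysis <- pa
  cfg$k <- cfg$k %||% "auto"
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$hp_cutoff_s <- cfg$hp_cutoff_s %||% 100
  cfg$retroicor_order <- cfg$retroicor_order %||% 4L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_inputs <- function(cfg, out_dir) {
  if (!is.null(cfg$simulate)) {
    pcfg <- do.call(phantom_config,
                    c(cfg$simulate, list(seed = substream_seed(cfg$seed, 1L))))
    ph <- simulate_phantom(pcfg)
    t_len <- n_timepoints(ph$func)
    physio <- simulate_physio(
      duration_s = t_len * pcfg$tr_s, hr_bpm = pcfg$cardiac_rate_hz * 60,
      rr_bpm = pcfg$resp_rate_hz * 60, jitter_frac = pcfg$rate_jitter_frac,
      seed = pcfg$seed)
    moco <- with_local_seed(substream_seed(cfg$seed, 2L), regressor_table(
      list(moco_x = cumsum(stats::rnorm(t_len, sd = 0.02)),
           moco_y = cumsum(stats::rnorm(t_len, sd = 0.02))), "motion"))
    task <- if (pcfg$task_amplitude > 0)
      regressor_table(list(task = ph$truth$task_timecourse), "task")
    else regressor_table()
    write_volume(ph$func, file.path(out_dir, "func.nii"))
    for (nm in c("cord", "csf", "cord_csf"))
      write_mask(ph$masks[[nm]], file.path(out_dir, paste0(nm, ".nii")))
    write_physio(physio$pulse, file.path(out_dir, "pulse.tsv"))
    write_physio(physio$resp, file.path(out_dir, "resp.tsv"))
    list(func = ph$func, cord_csf = ph$masks$cord_csf,
         cord = ph$masks$cord, csf = ph$masks$csf,
         motion = moco, task = task,
         pulse = physio$pulse, resp = physio$resp,
         horns = ph$masks$horns, truth = ph$truth)
  } else {
    ip <- cfg$inputs
    if (is.null(ip$func)) stop("config needs `simulate` or `inputs$func`",
                               call. = FALSE)
    func <- read_volume(ip$func)
    horns <- NULL
    if (!is.null(ip$horn_masks))
      horns <- lapply(ip$horn_masks, read_mask)
    list(
      func = func,
      cord_csf = read_mask(ip$cord_csf_mask),
      cord = read_mask(ip$cord_mask),
      csf = read_mask(ip$csf_mask),
      motion = if (!is.null(ip$motion))
        read_regressors(ip$motion, "motion") else regressor_table(),
      task = if (!is.null(ip$task))
        read_regressors(ip$task, "task") else regressor_table(),
      pulse = if (!is.null(ip$pulse))
        read_physio(ip$pulse, ip$physio_fs_hz, "pulse") else NULL,
      resp = if (!is.null(ip$resp))
        read_physio(ip$resp, ip$physio_fs_hz, "respiratory") else NULL,
      horns = horns)
  }
}

threshold_p_mask <- function(ft, alpha) {
  m <- array(0, ft$dims)
  m[ft$coords] <- as.numeric(ft$p < alpha)
  m
}

# write a 3D map (NA -> 0) with the parent series' geometry
write_volume_map <- function(map, v, path) {
  map[!is.finite(map)] <- 0
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- v$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# reconstruct a volume series holding residual timeseries (0 outside mask)
residual_volume <- function(fit, v) {
  arr <- array(0, c(fit$dims, fit$t_len))
  for (i in seq_len(nrow(fit$coords))) {
    co <- fit$coords[i, ]
    arr[co[1], co[2], co[3], ] <- fit$residuals[, i]
  }
  volume_series(arr, v$voxel_size_mm, v$tr_s, v$slice_times_s)
}

manifest_checksums <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(as.list(unname(sums)), files)
}
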