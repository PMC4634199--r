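#' Default pipeline configuration
#'
#' A nested list configuring an end-to-end run: cohort sizes and geometry,
#' ground-truth parameters for the simulator, seed coordinates, thresholds
#' (main-effect FWE alpha, voxelwise reporting threshold, nominal alpha,
#' Bonferroni family), coplot settings and output directory. All randomness
#' in a run derives from `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for run artifacts (`NULL` = no files).
#' @param n_carriers,n_controls cohort sizes.
#' @param n_volumes_rest resting-state volumes.
#' @param beta3 planted interaction coefficient (0 for a null cohort).
#' @return a named list (class `run_config`).
#' @export
default_config <- function(seed = 1L, out_dir = NULL, n_carriers = 106L,
                           n_controls = 111L, n_volumes_rest = 165L,
                           beta3 = -75) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohort = list(n_carriers = n_carriers, n_controls = n_controls,
                  n_sites = 4L, image_shape = c(24L, 28L, 24L),
                  voxel_size_mm = 4, tr_s = 3,
                  n_volumes_rest = n_volumes_rest, n_volumes_task = 190L),
    truth = list(beta3 = beta3),
    seeds_mm = list(rest_seed = c(42, 32, 28)),
    sphere_radius_mm = 4,
    drop_initial = 4L,
    thresholds = list(main_effect_fwe_alpha = 0.05,
                      connectivity_fwe_alpha = 0.05,
                      voxel_report_p = 0.001,
                      nominal_alpha = 0.05),
    bonferroni_family = c("caudate", "putamen", "gray", "white"),
    task_disease_load = "caudate",
    rest_disease_load = "gray",
    coplot = list(k = 4L, overlap = 0.5),
    write_images = FALSE
  ), class = "run_config")
}

#' Small demonstration configuration
#'
#' A reduced cohort (60 carriers, 40 controls, 80 resting volumes) that runs
#' the full pipeline in well under a minute while keeping the planted
#' effects detectable.
#'
#' @inheritParams default_config
#' @return a `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  cfg <- default_config(seed = seed, out_dir = out_dir, n_carriers = 60L,
                        n_controls = 40L, n_volumes_rest = 80L)
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and range checks; returns a character vector of problems (empty
#' means valid) and never raises or mutates state.
#'
#' @param config a `run_config` list.
#' @return character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- c("seed", "cohort", "thresholds", "bonferroni_family", "coplot")
  miss <- setdiff(need, names(config))
  if (length(miss))
    problems <- c(problems, paste0("missing key: ", miss))
  th <- config$thresholds
  for (nm in names(th))
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] >= 1)
      problems <- c(problems,
                    paste0("thresholds$", nm, " must be in (0,1)"))
  ch <- config$cohort
  for (nm in c("n_carriers", "n_controls"))
    if (!is.null(ch[[nm]]) && ch[[nm]] < 1)
      problems <- c(problems, paste0("cohort$", nm, " must be >= 1"))
  if (!is.null(ch$n_volumes_rest) && ch$n_volumes_rest < 20)
    problems <- c(problems, "cohort$n_volumes_rest must be >= 20")
  cp <- config$coplot
  if (!is.null(cp)) {
    if (is.null(cp$k) || cp$k < 1)
      problems <- c(problems, "coplot$k must be >= 1")
    if (!is.null(cp$overlap) && (cp$overlap < 0 || cp$overlap >= 1))
      problems <- c(problems, "coplot$overlap must be in [0,1)")
  }
  if (!length(config$bonferroni_family))
    problems <- c(problems, "bonferroni_family must be non-empty")
  for (p in config$input_paths)
    if (!file.exists(p))
      problems <- c(problems, paste0("input path does not exist: ", p))
  problems
}

config_spec <- function(config) {
  do.call(cohort_spec, config$cohort)
}

config_truth <- function(config) {
  args <- config$truth
  args$seed <- config$seed
  do.call(ground_truth, args)
}

#' Run the full compensation pipeline
#'
#' Executes simulate -> behaviour -> task main effect and voxelwise
#' compensation -> resting-state connectivity and cluster features ->
#' feature-level compensation fits with the pre-planned Bonferroni
#' correction and pattern classification -> conditioning-plot construction,
#' and returns (and optionally writes) a machine-readable report. Identical
#' config and seed give identical numeric report fields.
#'
#' @param config a `run_config` from [default_config()] / [demo_config()].
#' @return the run report (list), invisibly written as JSON when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config = default_config()) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  spec <- config_spec(config)
  truth <- config_truth(config)
  th <- config$thresholds
  report <- list(seed = config$seed,
                 timestamp = NULL,  # deliberately omitted: reports must be
                 stages = list())   # byte-identical across reruns
  t0 <- proc.time()[["elapsed"]]
  stage_time <- function() round(proc.time()[["elapsed"]] - t0, 2)

  # -- simulate ---------------------------------------------------------
  records <- generate_cohort_table(spec, truth)
  images <- generate_task_contrast_images(records, spec, truth)
  report$stages$simulate <- list(n_carriers = spec$n_carriers,
                                 n_controls = spec$n_controls,
                                 n_subjects = nrow(records),
                                 elapsed_s = stage_time())

  # -- behaviour --------------------------------------------------------
  records <- add_behavior_metrics(records)
  report$stages$behavior <- list(
    mean_dprime_2back = mean(records$dprime_2back),
    composite_var_explained =
      cognitive_composite(records[, cognitive_test_names()],
                          cognitive_test_orientation())$var_explained[1],
    elapsed_s = stage_time())

  # -- task: group main effect and voxelwise compensation ---------------
  grp <- group_onesample_t(images)
  me <- threshold_fwe(grp, alpha = th$main_effect_fwe_alpha,
                      method = "bonferroni")
  carriers <- records$group == "preHD"
  vw <- voxelwise_compensation(images[carriers], attr(me, "mask"),
                               records[carriers, ],
                               disease_load = config$task_disease_load,
                               y = "dprime_2back",
                               p_report = th$voxel_report_p)
  comp_vox_mm <- truth$effect_coords[[1]]
  ref <- vol_img(array(0, dim = spec$image_shape),
                 ras_affine(spec$image_shape, spec$voxel_size_mm))
  cv <- round(mm_to_vox(ref, comp_vox_mm)) + 1
  planted_fit <- fit_compensation(records[carriers, ],
                                  records$latent_f_task[carriers],
                                  disease_load = config$task_disease_load,
                                  y = "dprime_2back")
  planted_label <- classify_pattern(planted_fit,
                                    alpha = th$nominal_alpha)
  in_mask_p <- vw$p$data[vw$mask]
  min_p_idx <- which(vw$p$data == min(in_mask_p, na.rm = TRUE),
                     arr.ind = TRUE)
  report$stages$task <- list(
    mask_voxels = sum(attr(me, "mask")),
    n_clusters_main_effect = nrow(me),
    n_voxels_below_report_p = nrow(vw$voxels),
    planted_voxel = list(
      mm = comp_vox_mm,
      beta3 = vw$beta3$data[cv[1], cv[2], cv[3]],
      t = vw$t$data[cv[1], cv[2], cv[3]],
      p = vw$p$data[cv[1], cv[2], cv[3]],
      is_min_p = isTRUE(all(min_p_idx[1, ] == cv)),
      label = planted_label$label,
      slope_high_load = planted_label$slope_low_d,
      slope_low_load = planted_label$slope_high_d),
    elapsed_s = stage_time())

  # -- resting-state connectivity --------------------------------------
  zmaps <- generate_rest_series(records, spec, truth, fun = function(r, rec) {
    img <- drop_initial_volumes(r$img, config$drop_initial)
    nuis <- r$nuisance[-seq_len(config$drop_initial), , drop = FALSE]
    seed_correlation_map(img, config$seeds_mm$rest_seed, nuis,
                         radius_mm = config$sphere_radius_mm)
  })
  grp_z <- group_onesample_t(zmaps)
  cl <- threshold_fwe(grp_z, alpha = th$connectivity_fwe_alpha,
                      method = "bonferroni")
  # drop the seed's own cluster: seeds are reported, users can mask them
  seed_mm <- config$seeds_mm$rest_seed
  is_seed_cl <- sqrt((cl$peak_x - seed_mm[1])^2 + (cl$peak_y - seed_mm[2])^2 +
                       (cl$peak_z - seed_mm[3])^2) < 12
  target_found <- FALSE
  if (nrow(cl)) {
    labels <- attr(cl, "labels")
    tgt_vox <- round(mm_to_vox(ref, truth$rest_target_mm)) + 1
    tgt_lab <- labels[tgt_vox[1], tgt_vox[2], tgt_vox[3]]
    target_found <- tgt_lab > 0
  }
  report$stages$connectivity <- list(
    n_clusters = nrow(cl),
    n_seed_clusters = sum(is_seed_cl),
    clusters = as.data.frame(cl),
    target_cluster_found = target_found,
    elapsed_s = stage_time())

  # -- feature-level compensation fits ----------------------------------
  rest_results <- list()
  coplot_spec <- NULL
  if (any(!is_seed_cl)) {
    feats <- extract_cluster_means(cl, zmaps)
    for (j in which(!is_seed_cl)) {
      fj <- feats[carriers, j]
      fits <- lapply(config$bonferroni_family, function(dl)
        fit_compensation(records[carriers, ], fj, disease_load = dl,
                         y = "composite"))
      names(fits) <- config$bonferroni_family
      pvals <- vapply(fits, function(f) f$p, numeric(1))
      bf <- bonferroni_disease_load(pvals, alpha = th$nominal_alpha)
      labels <- lapply(fits, classify_pattern, alpha = th$nominal_alpha)
      rest_results[[colnames(feats)[j]]] <- list(
        cluster = as.list(cl[j, ]),
        fits = lapply(fits, function(f)
          list(beta1 = f$beta1, beta2 = f$beta2, beta3 = f$beta3,
               t = f$t, p = f$p, n = f$n)),
        bonferroni = bf,
        labels = lapply(labels, function(l) l$label))
      if (is.null(coplot_spec)) {
        dl_best <- config$rest_disease_load
        coplot_spec <- coplot_intervals(
          records[[dl_best]][carriers], fj,
          records$composite[carriers],
          k = config$coplot$k, overlap = config$coplot$overlap)
      }
    }
  }
  if (is.null(coplot_spec)) {
    coplot_spec <- coplot_intervals(
      records[[config$task_disease_load]][carriers],
      records$latent_f_task[carriers], records$dprime_2back[carriers],
      k = config$coplot$k, overlap = config$coplot$overlap)
  }
  report$stages$compensation <- list(
    rest_features = rest_results,
    coplot = list(k = coplot_spec$k, overlap = coplot_spec$overlap,
                  counts = coplot_spec$intervals$count,
                  slopes = coplot_spec$intervals$slope),
    elapsed_s = stage_time())

  # -- outputs ----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    write_coplot_json(coplot_spec, file.path(config$out_dir, "coplot.json"))
    if (isTRUE(config$write_images)) {
      write_vol_img(vw$t, file.path(config$out_dir, "compensation_t.nii.gz"))
      write_vol_img(vw$p, file.path(config$out_dir, "compensation_p.nii.gz"))
      write_vol_img(grp_z$t, file.path(config$out_dir, "connectivity_t.nii.gz"))
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}
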