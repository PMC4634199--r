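#' Type-I error calibration of the interaction test
#'
#' Simulates null cohorts (planted interaction coefficient exactly zero),
#' runs the full behavioural pathway (counts -> d-prime) and the
#' compensation fit at the planted feature, and reports the rejection rate
#' of `H0: beta3 = 0` at the nominal criterion.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_carriers carriers per cohort.
#' @param alpha nominal significance criterion (default 0.05).
#' @param seed master seed.
#' @return list: `rate`, `mc_se` (binomial Monte-Carlo s.e. at the nominal
#'   level), `n_cohorts`, `alpha`.
#' @export
calibrate_type1 <- function(n_cohorts = 1000L, n_carriers = 100L,
                            alpha = 0.05, seed = 1L) {
  spec <- cohort_spec(n_carriers = n_carriers, n_controls = 5L)
  rej <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    truth <- ground_truth(beta3 = 0, seed = child_seed(seed, 300000L + i))
    rec <- add_behavior_metrics(generate_cohort_table(spec, truth))
    rec <- rec[rec$group == "preHD", ]
    fit <- fit_compensation(rec, rec$latent_f_task, "caudate", "dprime_2back")
    rej[i] <- fit$p <= alpha
  }
  list(rate = mean(rej),
       mc_se = sqrt(alpha * (1 - alpha) / n_cohorts),
       n_cohorts = n_cohorts, alpha = alpha)
}

#' Parameter recovery of the planted interaction
#'
#' Simulates cohorts with the default planted `beta3`, fits the
#' compensation model on the measured d-prime outcome, and summarises
#' estimation bias and empirical 95% confidence-interval coverage.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_carriers carriers per cohort.
#' @param seed master seed.
#' @return list: `truth_beta3`, `mean_estimate`, `bias`, `bias_mc_se`,
#'   `coverage` (empirical 95% CI coverage), `n_cohorts`.
#' @export
calibrate_recovery <- function(n_cohorts = 200L, n_carriers = 200L,
                               seed = 1L) {
  spec <- cohort_spec(n_carriers = n_carriers, n_controls = 5L)
  est <- se <- df <- numeric(n_cohorts)
  b3 <- ground_truth()$beta3
  for (i in seq_len(n_cohorts)) {
    truth <- ground_truth(seed = child_seed(seed, 400000L + i))
    rec <- add_behavior_metrics(generate_cohort_table(spec, truth))
    rec <- rec[rec$group == "preHD", ]
    fit <- fit_compensation(rec, rec$latent_f_task, "caudate", "dprime_2back")
    est[i] <- fit$beta3
    se[i] <- fit$se["d:f"]
    df[i] <- fit$df_residual
  }
  tc <- stats::qt(0.975, df)
  list(truth_beta3 = b3,
       mean_estimate = mean(est),
       bias = mean(est) - b3,
       bias_mc_se = stats::sd(est) / sqrt(n_cohorts),
       coverage = mean(abs(est - b3) <= tc * se),
       n_cohorts = n_cohorts)
}

#' Planted-effect detection across seeded end-to-end runs
#'
#' Repeats the imaging pipeline with fresh seeds and measures two detection
#' rates: (i) how often the planted compensation voxel is the minimum-p
#' in-mask voxel of the voxelwise interaction map (task pathway: contrast
#' images, FWE main-effect mask, voxelwise fits), and (ii) how often the
#' planted resting-state target region falls inside an FWE-significant
#' cluster of the group connectivity map (rest pathway: per-subject seed
#' maps after nuisance regression, one-tailed group t, Bonferroni
#' threshold).
#'
#' @param n_runs number of independent seeded runs.
#' @param n_carriers carriers for the task pathway.
#' @param n_rest_subjects subjects for the rest pathway.
#' @param n_volumes_rest resting-state volumes acquired per subject.
#' @param seed master seed.
#' @param task,rest logical switches to run each pathway.
#' @return list with `task_top_rate`, `rest_cluster_rate`, per-run logical
#'   vectors, and the run count.
#' @export
detection_study <- function(n_runs = 20L, n_carriers = 100L,
                            n_rest_subjects = 60L, n_volumes_rest = 165L,
                            seed = 1L, task = TRUE, rest = TRUE) {
  task_hit <- rest_hit <- rep(NA, n_runs)
  for (run in seq_len(n_runs)) {
    run_seed <- child_seed(seed, 500000L + run)
    if (task) {
      spec <- cohort_spec(n_carriers = n_carriers, n_controls = 5L)
      truth <- ground_truth(seed = run_seed)
      rec <- add_behavior_metrics(generate_cohort_table(spec, truth))
      imgs <- generate_task_contrast_images(rec, spec, truth)
      grp <- group_onesample_t(imgs)
      me <- threshold_fwe(grp, alpha = 0.05, method = "bonferroni")
      ca <- rec$group == "preHD"
      vw <- voxelwise_compensation(imgs[ca], attr(me, "mask"), rec[ca, ],
                                   disease_load = "caudate",
                                   y = "dprime_2back")
      ref <- imgs[[1]]
      cv <- round(mm_to_vox(ref, truth$effect_coords[[1]])) + 1
      pm <- vw$p$data
      task_hit[run] <- isTRUE(
        pm[cv[1], cv[2], cv[3]] == min(pm, na.rm = TRUE))
    }
    if (rest) {
      spec_r <- cohort_spec(n_carriers = n_rest_subjects - 5L, n_controls = 5L,
                            n_volumes_rest = n_volumes_rest)
      truth_r <- ground_truth(seed = child_seed(run_seed, 7L))
      rec_r <- generate_cohort_table(spec_r, truth_r)
      zmaps <- generate_rest_series(rec_r, spec_r, truth_r,
                                    fun = function(r, rcd) {
        img <- drop_initial_volumes(r$img, 4L)
        nuis <- r$nuisance[-(1:4), , drop = FALSE]
        seed_correlation_map(img, truth_r$rest_seed_mm, nuis, radius_mm = 4)
      })
      grp_z <- group_onesample_t(zmaps)
      cl <- threshold_fwe(grp_z, alpha = 0.05, method = "bonferroni")
      found <- FALSE
      if (nrow(cl)) {
        labels <- attr(cl, "labels")
        ref <- zmaps[[1]]
        tv <- round(mm_to_vox(ref, truth_r$rest_target_mm)) + 1
        found <- labels[tv[1], tv[2], tv[3]] > 0
      }
      rest_hit[run] <- found
    }
  }
  list(task_top_rate = if (task) mean(task_hit) else NA,
       rest_cluster_rate = if (rest) mean(rest_hit) else NA,
       task_hits = task_hit, rest_hits = rest_hit, n_runs = n_runs)
}
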