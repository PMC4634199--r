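#' Study design of a synthetic cohort
#'
#' Sizes and imaging geometry for a simulated premanifest gene-carrier
#' cohort. Defaults mirror the study design being emulated: 106 carriers and
#' 111 controls across 4 sites, a 3 s repetition time and 165 resting-state
#' volumes, on a desk-scale 24 x 28 x 24 grid of 4 mm voxels.
#'
#' @param n_carriers number of premanifest gene-carriers (>= 1).
#' @param n_controls number of healthy controls (>= 1).
#' @param n_sites number of study sites.
#' @param image_shape integer 3-vector of voxel dimensions.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tr_s repetition time in seconds.
#' @param n_volumes_rest resting-state volumes acquired (before discarding
#'   steady-state scans).
#' @param n_volumes_task task-fMRI volumes acquired.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_carriers = 106L, n_controls = 111L, n_sites = 4L,
                        image_shape = c(24L, 28L, 24L), voxel_size_mm = 4,
                        tr_s = 3, n_volumes_rest = 165L,
                        n_volumes_task = 190L) {
  if (n_carriers < 1 || n_controls < 1 || n_sites < 1)
    stop("invalid-spec: counts must be >= 1")
  if (tr_s <= 0) stop("invalid-spec: tr_s must be positive")
  if (length(image_shape) != 3 || any(image_shape < 4))
    stop("invalid-spec: image_shape must be 3 dimensions of at least 4 voxels")
  structure(list(n_carriers = as.integer(n_carriers),
                 n_controls = as.integer(n_controls),
                 n_sites = as.integer(n_sites),
                 image_shape = as.integer(image_shape),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes_rest = as.integer(n_volumes_rest),
                 n_volumes_task = as.integer(n_volumes_task)),
            class = "cohort_spec")
}

#' Ground-truth parameters of the synthetic cohort
#'
#' Coefficients of the planted compensation relationship
#' `y = alpha + beta1 d + beta2 f + beta3 (d - d_ref)(f - f_ref) +
#' gamma c + e`, where `y` is task performance (d-prime scale), `d` the
#' caudate volume fraction of intracranial volume, `f` the planted
#' task-fMRI feature, and `c` the covariates (age, gender, education, CPO,
#' plus site shifts). The interaction is centred at reference values
#' (`d_ref`, `f_ref`) so that changing `beta3` (including to 0 for null
#' cohorts) alters the conditional slope structure without shifting the
#' performance mean out of the d-prime range; `beta3` is still exactly the
#' coefficient of the raw `d:f` product an analyst estimates, since
#' centring only reparameterises the main effects and intercept. A negative
#' `beta3` makes the performance-activity slope steepest at low volume
#' (high structural disease load), i.e. a compensatory pattern. Additional
#' fields parameterise the planted resting-state network: per-subject
#' seed-target coupling (mean/sd) and an analogous interaction of coupling
#' with grey-matter fraction in the latent cognition score.
#'
#' @param alpha intercept (performance units).
#' @param beta1 disease-load main effect (per unit volume fraction).
#' @param beta2 fMRI-feature main effect (slope at the reference load).
#' @param beta3 interaction coefficient (per unit volume fraction).
#' @param d_ref,f_ref centring references for the planted interaction
#'   (typical caudate fraction and feature mean).
#' @param gamma named covariate coefficients (`age`, `genderM`, `education`,
#'   `cpo`); age and education enter centred (45 years, level 3).
#' @param sigma_e residual standard deviation (> 0).
#' @param effect_coords list of mm coordinates of planted task main-effect
#'   regions; the first is the designated compensation coordinate.
#' @param rest_coupling_mean,rest_coupling_sd per-subject seed-target
#'   coupling distribution (correlation scale).
#' @param rest_beta coefficients (`alpha`, `beta1`, `beta2`, `beta3`) of the
#'   latent-cognition analogue of the compensation equation, with grey-matter
#'   fraction as disease load and coupling as the fMRI feature.
#' @param rest_sigma residual sd of latent cognition.
#' @param rest_seed_mm,rest_target_mm mm coordinates of the resting-state
#'   seed (right DLPFC-like) and planted target region.
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(alpha = 0.03, beta1 = 60, beta2 = 0.10, beta3 = -75,
                         d_ref = 0.0044, f_ref = 2,
                         gamma = c(age = -0.004, genderM = 0.02,
                                   education = 0.01, cpo = -0.10),
                         sigma_e = 0.08,
                         effect_coords = list(c(36, -56, 44), c(-32, 20, 28)),
                         rest_coupling_mean = 0.6, rest_coupling_sd = 0.1,
                         rest_beta = c(alpha = -2, beta1 = 5, beta2 = 0.8,
                                       beta3 = -52),
                         rest_gray_ref = 0.44,
                         rest_sigma = 0.5,
                         rest_seed_mm = c(42, 32, 28),
                         rest_target_mm = c(-34, -20, -12),
                         seed = 42L) {
  if (sigma_e <= 0) stop("invalid-spec: sigma_e must be positive")
  stopifnot(is.list(effect_coords), length(effect_coords) >= 1,
            all(lengths(effect_coords) == 3))
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 d_ref = d_ref, f_ref = f_ref,
                 gamma = gamma, sigma_e = sigma_e,
                 effect_coords = effect_coords,
                 rest_gray_ref = rest_gray_ref,
                 rest_coupling_mean = rest_coupling_mean,
                 rest_coupling_sd = rest_coupling_sd,
                 rest_beta = rest_beta, rest_sigma = rest_sigma,
                 rest_seed_mm = rest_seed_mm, rest_target_mm = rest_target_mm,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# deterministic child seed; stays below 2^31
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + tag) %% 2147483647)
}

# truncated normal by resampling (vectorised)
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  it <- 0L
  while (length(bad) && it < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
    it <- it + 1L
  }
  pmin(pmax(x, lower + 1e-9), upper - 1e-9)
}

#' Names of the nine simulated cognitive tests
#'
#' `trail_b` and `paced_tapping_sd` are timing/error scores where lower is
#' better; the rest are higher-is-better.
#' @return character vector of nine column names.
#' @export
cognitive_test_names <- function() {
  c("sdmt", "stroop_word", "trail_b", "verbal_fluency", "spot_change",
    "mental_rotation", "map_search", "cancellation", "paced_tapping_sd")
}

#' Orientation flags for the simulated battery
#' @return named logical vector, `TRUE` where higher scores mean better
#'   performance.
#' @export
cognitive_test_orientation <- function() {
  stats::setNames(!cognitive_test_names() %in% c("trail_b", "paced_tapping_sd"),
                  cognitive_test_names())
}

#' Generate a synthetic cohort table
#'
#' Simulates one row per subject: demographics, CAG repeat length and the
#' disease-burden score `age * (CAG - 35.5)` (carriers are resampled until
#' the recruitment filter burden > 250 holds), a cumulative probability of
#' onset (CPO) that rises logistically with burden, regional volume
#' fractions of intracranial volume that decline linearly in CPO, a nine-test
#' cognitive battery driven by a single latent cognition factor, n-back hit
#' and false-alarm counts whose hit-minus-false-alarm rate realises the
#' planted compensation equation, motor scores (total motor score,
#' grip-force variability), and the latent fMRI features (`latent_f_task`,
#' `latent_f_rest`) that the image generators plant.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [ground_truth()].
#' @return data.frame with `spec$n_carriers + spec$n_controls` rows.
#' @export
generate_cohort_table <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  set.seed(child_seed(truth$seed, 1L))
  n_ca <- spec$n_carriers; n_co <- spec$n_controls
  n <- n_ca + n_co

  # carriers: CAG >= 40, disease burden age*(CAG-35.5) > 250 (recruitment)
  age_ca <- rnorm_trunc(n_ca, 42.8, 9.1, 18, 65)
  cag_ca <- sample(40:50, n_ca, replace = TRUE,
                   prob = c(8, 10, 9, 7, 5, 3, 2, 1.5, 1, 0.7, 0.5))
  dbs <- age_ca * (cag_ca - 35.5)
  bad <- which(dbs <= 250)
  it <- 0L
  while (length(bad) && it < 200L) {
    age_ca[bad] <- rnorm_trunc(length(bad), 42.8, 9.1, 18, 65)
    cag_ca[bad] <- sample(40:50, length(bad), replace = TRUE,
                          prob = c(8, 10, 9, 7, 5, 3, 2, 1.5, 1, 0.7, 0.5))
    dbs[bad] <- age_ca[bad] * (cag_ca[bad] - 35.5)
    bad <- which(dbs <= 250)
    it <- it + 1L
  }
  age_co <- rnorm_trunc(n_co, 48.1, 10.7, 18, 70)

  group <- rep(c("preHD", "control"), c(n_ca, n_co))
  age <- c(age_ca, age_co)
  cag <- c(cag_ca, rep(NA_integer_, n_co))
  burden <- c(dbs, rep(0, n_co))
  # CPO surrogate: logistic in disease burden, 0 for controls
  cpo <- ifelse(group == "preHD", stats::plogis((burden - 350) / 60), 0)

  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  site <- sample(seq_len(spec$n_sites), n, replace = TRUE)
  education <- sample(1:6, n, replace = TRUE,
                      prob = c(0.05, 0.1, 0.2, 0.3, 0.25, 0.1))
  icv <- stats::rnorm(n, 1450, 120)

  # atrophy: fraction means decline linearly in CPO
  caudate <- 0.0048 - 0.0016 * cpo + stats::rnorm(n, 0, 5e-4)
  putamen <- 0.0055 - 0.0018 * cpo + stats::rnorm(n, 0, 6e-4)
  gray    <- 0.46  - 0.05   * cpo + stats::rnorm(n, 0, 0.02)
  white   <- 0.33  - 0.03   * cpo + stats::rnorm(n, 0, 0.015)
  caudate <- pmin(pmax(caudate, 1e-4), 1 - 1e-4)
  putamen <- pmin(pmax(putamen, 1e-4), 1 - 1e-4)
  gray    <- pmin(pmax(gray, 1e-4), 1 - 1e-4)
  white   <- pmin(pmax(white, 1e-4), 1 - 1e-4)

  site_shift <- stats::rnorm(spec$n_sites, 0, 0.02)
  cov_term <- truth$gamma["age"] * (age - 45) +
    truth$gamma["genderM"] * (gender == "M") +
    truth$gamma["education"] * (education - 3) +
    truth$gamma["cpo"] * cpo + site_shift[site]

  # planted task feature and forward generation of task performance from the
  # compensation equation, interaction centred at (d_ref, f_ref)
  f_task <- stats::rnorm(n, truth$f_ref, 1)
  y_task <- truth$alpha + truth$beta1 * caudate + truth$beta2 * f_task +
    truth$beta3 * (caudate - truth$d_ref) * (f_task - truth$f_ref) +
    cov_term + stats::rnorm(n, 0, truth$sigma_e)

  # n-back counts realising y_task as hit rate minus false-alarm rate;
  # the false-alarm rate absorbs boundary cases so that any y in [-1, 1] is
  # represented exactly up to count rounding
  y_t <- pmin(pmax(y_task, -1), 1)
  nb2_targets <- 24L; nb2_nontargets <- 48L
  p_fa2 <- stats::runif(n, 0.01, 0.05)
  p_hit2 <- pmin(pmax(y_t + p_fa2, 0), 1)
  p_fa2 <- p_hit2 - y_t
  nb2_hits <- as.integer(round(p_hit2 * nb2_targets))
  nb2_fa <- as.integer(round(p_fa2 * nb2_nontargets))
  y_t1 <- pmin(pmax(y_task + 0.15, -1), 1)
  nb1_targets <- 24L; nb1_nontargets <- 48L
  p_fa1 <- stats::runif(n, 0.005, 0.05)
  p_hit1 <- pmin(pmax(y_t1 + p_fa1, 0), 1)
  p_fa1 <- p_hit1 - y_t1
  nb1_hits <- as.integer(round(p_hit1 * nb1_targets))
  nb1_fa <- as.integer(round(p_fa1 * nb1_nontargets))

  # planted resting coupling and latent cognition via the same interaction
  # structure on grey-matter fraction
  f_rest <- rnorm_trunc(n, truth$rest_coupling_mean, truth$rest_coupling_sd,
                        -0.9, 0.9)
  rb <- truth$rest_beta
  cognition <- rb[["alpha"]] + rb[["beta1"]] * gray + rb[["beta2"]] * f_rest +
    rb[["beta3"]] * (gray - truth$rest_gray_ref) *
    (f_rest - truth$rest_coupling_mean) +
    cov_term + stats::rnorm(n, 0, truth$rest_sigma)

  # nine-test battery from a single latent factor; two tests inverted
  loadings <- seq(0.6, 0.9, length.out = 9)
  orient <- cognitive_test_orientation()
  battery <- sapply(seq_len(9), function(j)
    loadings[j] * cognition + stats::rnorm(n, 0, 0.3))
  colnames(battery) <- cognitive_test_names()
  for (nm in names(orient)[!orient]) battery[, nm] <- -battery[, nm]

  tms <- pmax(0, 2 + 10 * cpo + stats::rnorm(n, 0, 1.5))
  gfv <- pmax(0.005, 0.08 + 0.1 * cpo + stats::rnorm(n, 0, 0.02))

  out <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)), group = group, site = site,
    age = age, gender = gender, education = education, cag = cag,
    disease_burden = burden, cpo = cpo, icv = icv,
    caudate = caudate, putamen = putamen, gray = gray, white = white,
    caudate_vol = caudate * icv, putamen_vol = putamen * icv,
    gray_vol = gray * icv, white_vol = white * icv,
    nb1_targets = nb1_targets, nb1_hits = nb1_hits,
    nb1_nontargets = nb1_nontargets, nb1_false_alarms = nb1_fa,
    nb2_targets = nb2_targets, nb2_hits = nb2_hits,
    nb2_nontargets = nb2_nontargets, nb2_false_alarms = nb2_fa,
    tms = tms, gfv = gfv,
    latent_f_task = f_task, latent_f_rest = f_rest,
    latent_cognition = cognition, latent_y_task = y_task,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(battery))
}

# round a mm coordinate to the nearest voxel index, erroring outside the grid
coord_to_voxel <- function(coord_mm, shape, affine) {
  img <- vol_img(array(0, dim = shape), affine)
  v <- round(mm_to_vox(img, coord_mm))
  if (any(v < 0) || any(v >= shape))
    stop("coordinate error: effect coordinate outside the image")
  as.integer(v) + 1L  # 1-based array index
}

#' Generate per-subject task contrast images
#'
#' Each 3D map is spatially smoothed Gaussian background noise (6 mm FWHM)
#' plus a Gaussian-profile main-effect blob of subject-varying amplitude at
#' every `truth$effect_coords` location; at the first (compensation)
#' coordinate the voxel value is replaced by the subject's planted feature
#' `latent_f_task`, so that the compensation equation holds exactly at that
#' voxel by construction.
#'
#' @param records cohort table from [generate_cohort_table()].
#' @param spec a [cohort_spec()].
#' @param truth a [ground_truth()].
#' @return named list of 3D `vol_img` (names are subject ids).
#' @export
generate_task_contrast_images <- function(records, spec, truth) {
  stopifnot(is.data.frame(records), inherits(spec, "cohort_spec"),
            inherits(truth, "ground_truth"))
  shape <- spec$image_shape
  affine <- ras_affine(shape, spec$voxel_size_mm)
  centers <- lapply(truth$effect_coords, coord_to_voxel, shape = shape,
                    affine = affine)
  comp_vox <- centers[[1]]
  grid <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                      k = seq_len(shape[3]))
  profiles <- lapply(centers, function(ctr) {
    d2 <- (grid$i - ctr[1])^2 + (grid$j - ctr[2])^2 + (grid$k - ctr[3])^2
    array(exp(-d2 / (2 * 2^2)), dim = shape)
  })
  imgs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    set.seed(child_seed(truth$seed, 10000L + i))
    noise <- vol_img(array(stats::rnorm(prod(shape)), dim = shape), affine)
    bg <- smooth_img(noise, 6)$data
    for (pr in profiles) bg <- bg + (2 + stats::rnorm(1, 0, 0.5)) * pr
    bg[comp_vox[1], comp_vox[2], comp_vox[3]] <- records$latent_f_task[i]
    imgs[[i]] <- vol_img(bg, affine)
  }
  names(imgs) <- records$id
  imgs
}

#' Generate one subject's resting-state series and nuisance table
#'
#' A shared latent time course drives a seed region; a target region carries
#' a mixture of the seed latent and independent noise with mixing weight
#' equal to the subject's planted coupling `latent_f_rest`, so that the
#' seed-target correlation equals the coupling in expectation. Global white
#' matter and CSF confound time courses are added to every voxel and
#' reported, together with six synthetic motion regressors, in the nuisance
#' table.
#'
#' @param record one row of the cohort table.
#' @param spec a [cohort_spec()].
#' @param truth a [ground_truth()].
#' @param subject_index integer used to derive the per-subject seed.
#' @return list with `img` (4D `vol_img`), `nuisance` (data.frame with
#'   columns motion1..6, wm, csf), and `latents` (seed/target latent series).
#' @export
generate_rest_subject <- function(record, spec, truth, subject_index) {
  if (spec$n_volumes_rest < 20L)
    stop("invalid-spec: n_volumes_rest must be at least 20")
  shape <- spec$image_shape
  affine <- ras_affine(shape, spec$voxel_size_mm)
  TT <- spec$n_volumes_rest
  set.seed(child_seed(truth$seed, 20000L + subject_index))
  s <- stats::rnorm(TT)                    # seed latent
  q <- stats::rnorm(TT)                    # target-specific latent
  rho <- record$latent_f_rest
  tgt <- rho * s + sqrt(1 - rho^2) * q
  wm <- stats::rnorm(TT)
  csf <- stats::rnorm(TT)
  motion <- sapply(1:6, function(j) cumsum(stats::rnorm(TT, 0, 0.05)))
  colnames(motion) <- paste0("motion", 1:6)

  V <- prod(shape)
  dat <- matrix(stats::rnorm(V * TT), nrow = V, ncol = TT)
  ref <- vol_img(array(0, dim = shape), affine)
  seed_vox <- extract_sphere_voxels(ref, truth$rest_seed_mm, 6)
  tgt_vox <- extract_sphere_voxels(ref, truth$rest_target_mm, 6)
  dat[seed_vox, ] <- 0.3 * dat[seed_vox, , drop = FALSE] +
    matrix(s, length(seed_vox), TT, byrow = TRUE)
  dat[tgt_vox, ] <- 0.3 * dat[tgt_vox, , drop = FALSE] +
    matrix(tgt, length(tgt_vox), TT, byrow = TRUE)
  dat <- dat + matrix(0.7 * wm + 0.7 * csf, V, TT, byrow = TRUE)

  list(img = vol_img(array(dat, dim = c(shape, TT)), affine),
       nuisance = data.frame(motion, wm = wm, csf = csf),
       latents = list(seed = s, target = tgt))
}

# voxel linear indices within radius_mm of a mm coordinate
extract_sphere_voxels <- function(ref, center_mm, radius_mm) {
  mm <- voxel_grid_mm(ref)
  which((mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
          (mm[, 3] - center_mm[3])^2 <= radius_mm^2)
}

#' Generate resting-state series for every subject
#'
#' Convenience wrapper over [generate_rest_subject()]. When `fun` is given
#' it is applied to each subject's result and only the return values are
#' kept, so large 4D arrays never accumulate in memory.
#'
#' @param records cohort table.
#' @param spec a [cohort_spec()].
#' @param truth a [ground_truth()].
#' @param fun optional function of (subject_result, record) applied per
#'   subject.
#' @return named list of per-subject results (or of `fun`'s values).
#' @export
generate_rest_series <- function(records, spec, truth, fun = NULL) {
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- generate_rest_subject(records[i, ], spec, truth, i)
    out[[i]] <- if (is.null(fun)) r else fun(r, records[i, ])
  }
  names(out) <- records$id
  out
}

#' Write a cohort to disk (CSV table, NIfTI images, manifest)
#'
#' @param records cohort table.
#' @param dir output directory (created if needed).
#' @param images optional named list of `vol_img` to write as
#'   `<id>_contrast.nii.gz`.
#' @param truth optional [ground_truth()] recorded in the manifest.
#' @return path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(records, dir, images = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  paths <- list(cohort = csv)
  if (!is.null(images)) {
    img_dir <- file.path(dir, "contrast")
    dir.create(img_dir, showWarnings = FALSE)
    paths$contrast <- vapply(names(images), function(id) {
      p <- file.path(img_dir, paste0(id, "_contrast.nii.gz"))
      write_vol_img(images[[id]], p)
      p
    }, character(1))
  }
  manifest <- list(files = paths,
                   ground_truth = if (!is.null(truth)) unclass(truth))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}
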