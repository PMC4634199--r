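make_fit_records <- function(n = 120, seed = 1) {
  set.seed(seed)
  data.frame(
    age = rnorm(n, 45, 9), gender = sample(c("F", "M"), n, TRUE),
    site = sample(1:3, n, TRUE), education = sample(1:6, n, TRUE),
    cpo = runif(n, 0, 0.9),
    caudate = runif(n, 0.003, 0.006),
    putamen = runif(n, 0.004, 0.007),
    gray = runif(n, 0.38, 0.49), white = runif(n, 0.28, 0.36))
}

test_that("noiseless data are recovered to machine precision", {
  rec <- make_fit_records()
  f <- rnorm(nrow(rec), 2, 1)
  rec$y <- 0.1 + 50 * rec$caudate + 0.3 * f - 40 * rec$caudate * f +
    0.01 * rec$age - 0.05 * rec$cpo
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    fit_compensation(rec, f, "caudate", "y", covariates = c("age", "cpo")))
  expect_equal(fit$beta1, 50, tolerance = 1e-8)
  expect_equal(fit$beta2, 0.3, tolerance = 1e-8)
  expect_equal(fit$beta3, -40, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-8)
})

test_that("fit matches the pseudoinverse oracle with noise and full covariates", {
  rec <- make_fit_records(seed = 2)
  f <- rnorm(nrow(rec), 2, 1)
  rec$y <- 0.2 + 30 * rec$caudate + 0.2 * f - 30 * rec$caudate * f +
    rnorm(nrow(rec), 0, 0.1)
  fit <- fit_compensation(rec, f, "caudate", "y")
  X <- comp_design(rec, f, "caudate")
  oracle <- pinv_fit(X, rec$y, ncol(X))
  expect_equal(fit$beta3, oracle$beta, tolerance = 1e-8)
  expect_equal(fit$t, oracle$t, tolerance = 1e-8)
  expect_equal(fit$p, oracle$p, tolerance = 1e-8)
})

test_that("the beta3 test is invariant to centring d and rescaling f", {
  rec <- make_fit_records(seed = 3)
  f <- rnorm(nrow(rec), 2, 1)
  rec$y <- 0.2 + 30 * rec$caudate + 0.2 * f - 35 * rec$caudate * f +
    rnorm(nrow(rec), 0, 0.1)
  base <- fit_compensation(rec, f, "caudate", "y")
  cen <- rec
  cen$caudate <- cen$caudate - mean(cen$caudate)
  centred <- fit_compensation(cen, f, "caudate", "y")
  expect_equal(centred$t, base$t, tolerance = 1e-8)
  expect_equal(centred$p, base$p, tolerance = 1e-8)
  scaled <- fit_compensation(rec, 3.7 * f + 2, "caudate", "y")
  expect_equal(scaled$p, base$p, tolerance = 1e-8)
  expect_equal(scaled$beta3 * 3.7, base$beta3, tolerance = 1e-8)
})

test_that("collinear designs raise a diagnostic and small n is rejected", {
  rec <- make_fit_records(seed = 4)
  f <- rec$caudate * 1000   # f proportional to d
  rec$y <- rnorm(nrow(rec))
  expect_error(fit_compensation(rec, f, "caudate", "y"), "collinearity")
  expect_error(fit_compensation(rec[1:12, ], rnorm(12), "caudate", "y"),
               "complete cases")
})

test_that("voxelwise mapping reduces to the single fit and matches the oracle", {
  spec <- small_spec()
  truth <- small_truth(seed = 6)
  rec <- add_behavior_metrics(generate_cohort_table(spec, truth))
  imgs <- generate_task_contrast_images(rec, spec, truth)
  ca <- rec$group == "preHD"
  d <- spatial_dim(imgs[[1]])
  # single-voxel mask equals fit_compensation at that voxel
  mask1 <- array(FALSE, d); mask1[4, 5, 6] <- TRUE
  vw1 <- voxelwise_compensation(imgs[ca], mask1, rec[ca, ], "caudate",
                                "dprime_2back")
  fvox <- vapply(imgs[ca], function(m) m$data[4, 5, 6], numeric(1))
  single <- fit_compensation(rec[ca, ], fvox, "caudate", "dprime_2back")
  expect_equal(vw1$t$data[4, 5, 6], single$t, tolerance = 1e-8)
  expect_equal(vw1$p$data[4, 5, 6], single$p, tolerance = 1e-8)
  expect_equal(vw1$beta3$data[4, 5, 6], single$beta3, tolerance = 1e-8)
  # full-volume map equals the per-voxel pseudoinverse oracle
  vw <- voxelwise_compensation(imgs[ca], NULL, rec[ca, ], "caudate",
                               "dprime_2back")
  F <- vapply(imgs[ca], function(m) as.numeric(m$data), numeric(prod(d)))
  rc <- rec[ca, ]
  check <- sample(prod(d), 50)
  for (v in check) {
    X <- comp_design(rc, F[v, ], "caudate")
    o <- pinv_fit(X, rc$dprime_2back, ncol(X))
    expect_equal(as.numeric(vw$t$data)[v], o$t, tolerance = 1e-8)
  }
  expect_error(voxelwise_compensation(imgs[ca], array(FALSE, d), rec[ca, ]),
               "empty mask")
})

test_that("Bonferroni across the four disease loads reproduces the survive/not split", {
  res <- bonferroni_disease_load(c(gray = 0.010, putamen = 0.019,
                                   caudate = 0.034, white = 0.049))
  expect_true(all(res$significant_raw))
  expect_equal(res$significant_adjusted,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$p_adjusted, c(0.040, 0.076, 0.136, 0.196))
  one <- bonferroni_disease_load(c(x = 0.04), alpha = 0.05)
  expect_true(one$significant_adjusted)
  expect_error(bonferroni_disease_load(numeric(0)), "empty family")
})

test_that("pattern classification follows the slope-by-load definition", {
  rec <- make_fit_records(seed = 7)
  mkfit <- function(beta2, beta3, p) {
    structure(list(beta2 = beta2, beta3 = beta3, p = p,
                   model = list(model = data.frame(d = rec$caudate))),
              class = "compensation_fit")
  }
  # positive slope at high load fading with volume: compensatory
  cl <- classify_pattern(mkfit(0.5, -80, 0.01), 0.003, 0.006)
  expect_equal(cl$label, "compensatory")
  expect_gt(cl$slope_low_d, cl$slope_high_d)
  # negative slope at high load strengthening with volume: non-compensatory
  cl2 <- classify_pattern(mkfit(-0.1, 60, 0.01), 0.003, 0.006)
  expect_equal(cl2$label, "non-compensatory")
  # not significant: none
  expect_equal(classify_pattern(mkfit(0.5, -80, 0.5), 0.003, 0.006)$label,
               "none")
  expect_error(classify_pattern(mkfit(0.5, -80, 0.01), 0.006, 0.003),
               "d_low")
  # joint negation of (f, beta2, beta3) maps labels deterministically
  for (b in list(c(0.5, -80), c(-0.1, 60), c(0.2, -10))) {
    l1 <- classify_pattern(mkfit(b[1], b[2], 0.01), 0.003, 0.006)$label
    l2 <- classify_pattern(mkfit(-b[1], -b[2], 0.01), 0.003, 0.006)$label
    expect_equal(l2, switch(l1, compensatory = "non-compensatory",
                            `non-compensatory` = l1, none = "none"),
                 label = paste(b, collapse = ","))
  }
})

test_that("coplot intervals partition exactly when overlap is zero", {
  set.seed(8)
  d <- rnorm(12); f <- rnorm(12); y <- rnorm(12)
  cp <- coplot_intervals(d, f, y, k = 3, overlap = 0)
  expect_equal(cp$intervals$count, c(4, 4, 4))
  expect_equal(sort(unlist(cp$indices)), 1:12)
  expect_equal(length(intersect(cp$indices[[1]], cp$indices[[2]])), 0)
  # k = 1: single interval, slope equals the global regression
  cp1 <- coplot_intervals(d, f, y, k = 1)
  expect_equal(cp1$intervals$count, 12)
  expect_equal(cp1$intervals$slope, unname(coef(lm(y ~ f))[2]))
  expect_error(coplot_intervals(d[1:5], f[1:5], y[1:5], k = 3),
               "too-few-observations")
  expect_error(coplot_intervals(d, f, y, k = 2, overlap = 1), "overlap")
})

test_that("overlapping intervals satisfy the equal-count properties", {
  set.seed(9)
  n <- 100
  d <- rnorm(n); f <- rnorm(n); y <- rnorm(n)
  cp <- coplot_intervals(d, f, y, k = 4, overlap = 0.5)
  m <- n / (4 * 0.5 + 0.5)
  expect_true(all(abs(cp$intervals$count - m) <= 1))
  shared <- vapply(1:3, function(j)
    length(intersect(cp$indices[[j]], cp$indices[[j + 1]])), numeric(1))
  expect_true(all(abs(shared - m * 0.5) <= 2))
  # union covers all observations; intervals ordered by d
  expect_setequal(unlist(cp$indices), 1:n)
  expect_true(all(diff(cp$intervals$lower) > 0))
  expect_true(all(cp$intervals$upper >= cp$intervals$lower))
  # brute-force: interval bounds really select the counted points
  for (j in 1:4) {
    sel <- cp$indices[[j]]
    expect_true(all(d[sel] >= cp$intervals$lower[j] - 1e-12 &
                      d[sel] <= cp$intervals$upper[j] + 1e-12))
  }
  # per-interval display slope equals a direct least-squares fit
  j <- 2
  sel <- cp$indices[[j]]
  expect_equal(cp$intervals$slope[j], unname(coef(lm(y[sel] ~ f[sel]))[2]))
})

test_that("conditioning plots render without error", {
  set.seed(21)
  d <- runif(40, 0.003, 0.006); f <- rnorm(40); y <- 0.3 * f + rnorm(40)
  cp <- coplot_intervals(d, f, y, k = 3, overlap = 0.5)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(cp, d, f, y))
  grDevices::dev.off()
  expect_gt(file.info(path)$size, 0)
})

test_that("interaction p-values hold their nominal level under permutation-like nulls", {
  # property check at modest scale: null beta3, many cohorts
  spec <- cohort_spec(n_carriers = 80, n_controls = 5)
  p <- numeric(60)
  for (i in 1:60) {
    truth <- ground_truth(beta3 = 0, seed = 9000 + i)
    rec <- add_behavior_metrics(generate_cohort_table(spec, truth))
    rec <- rec[rec$group == "preHD", ]
    p[i] <- fit_compensation(rec, rec$latent_f_task, "caudate",
                             "dprime_2back")$p
  }
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
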