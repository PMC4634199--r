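make_rest_img <- function(seed = 1, shape = c(6, 6, 6), TT = 60, vs = 4) {
  set.seed(seed)
  vol_img(array(rnorm(prod(shape) * TT), c(shape, TT)),
          ras_affine(shape, vs))
}

test_that("a voxel identical to the seed maps to the documented z ceiling", {
  img <- make_rest_img(1)
  center <- vox_to_mm(img, c(3, 3, 3))
  sph <- extract_sphere(img, center, 1)
  # make a single-voxel seed; copy its series to a distant voxel
  img$data[6, 6, 6, ] <- img$data[4, 4, 4, ]
  z <- seed_correlation_map(img, center, nuisance = NULL, radius_mm = 1)
  expect_equal(z$data[4, 4, 4], 10)
  expect_equal(z$data[6, 6, 6], 10)
  expect_true(all(is.finite(z$data)))
})

test_that("partial correlation matches a manual residualisation oracle", {
  img <- make_rest_img(2)
  TT <- dim(img$data)[4]
  nuis <- data.frame(wm = rnorm(TT), csf = rnorm(TT))
  center <- vox_to_mm(img, c(3, 3, 3))
  z <- seed_correlation_map(img, center, nuis, radius_mm = 1)
  seed <- img$data[4, 4, 4, ]
  for (v in list(c(1, 2, 3), c(5, 5, 2))) {
    y <- img$data[v[1], v[2], v[3], ]
    rs <- resid(lm(seed ~ wm + csf, nuis))
    ry <- resid(lm(y ~ wm + csf, nuis))
    expect_equal(z$data[v[1], v[2], v[3]], atanh(cor(rs, ry)),
                 tolerance = 1e-10)
  }
})

test_that("a voxel made of pure confound is silenced by nuisance regression", {
  img <- make_rest_img(3)
  TT <- dim(img$data)[4]
  wm <- rnorm(TT)
  img$data[2, 2, 2, ] <- wm
  center <- vox_to_mm(img, c(4, 4, 4))
  z <- seed_correlation_map(img, center, data.frame(wm = wm), radius_mm = 1)
  expect_lt(abs(z$data[2, 2, 2]), 1e-8)
  # collinear nuisance triggers the degeneracy error
  expect_error(
    seed_correlation_map(img, center,
                         data.frame(s = img$data[5, 5, 5, ]), radius_mm = 1),
    "degenerate-nuisance")
})

test_that("group one-sample t matches t.test and handles zero variance", {
  set.seed(4)
  shape <- c(4, 4, 4)
  maps <- lapply(1:12, function(i)
    vol_img(array(rnorm(prod(shape)), shape)))
  grp <- group_onesample_t(maps)
  v <- c(2, 3, 4)
  vals <- vapply(maps, function(m) m$data[v[1], v[2], v[3]], numeric(1))
  tt <- t.test(vals, alternative = "greater")
  expect_equal(grp$t$data[v[1], v[2], v[3]], unname(tt$statistic),
               tolerance = 1e-10)
  expect_equal(grp$p$data[v[1], v[2], v[3]], tt$p.value, tolerance = 1e-10)
  # identical constant maps: capped t, p -> 0
  const <- lapply(1:5, function(i) vol_img(array(0.3, shape)))
  g2 <- group_onesample_t(const)
  expect_true(all(g2$t$data == 1e6))
  expect_true(all(g2$p$data < 1e-12))
  # sign flip kills one-tailed significance
  neg <- lapply(maps, function(m) vol_img(-m$data, m$affine))
  g3 <- group_onesample_t(neg)
  sig_pos <- sum(grp$p$data < 0.05)
  expect_equal(sum(g3$p$data < 0.05 & grp$p$data < 0.05), 0)
  bad <- maps
  bad[[2]] <- vol_img(maps[[2]]$data, ras_affine(shape, 2))
  expect_error(group_onesample_t(bad), "geometry")
})

test_that("null maps almost never survive FWE and uncorrected alpha=1 keeps all", {
  set.seed(5)
  shape <- c(5, 5, 5)
  empty <- 0
  n_sim <- 40
  for (s in 1:n_sim) {
    maps <- lapply(1:10, function(i) vol_img(array(rnorm(prod(shape)), shape)))
    grp <- group_onesample_t(maps)
    cl <- threshold_fwe(grp, alpha = 0.05, method = "bonferroni")
    empty <- empty + (nrow(cl) == 0)
  }
  expect_gte(empty / n_sim, 0.90)
  maps <- lapply(1:8, function(i) vol_img(array(rnorm(prod(shape)), shape)))
  grp <- group_onesample_t(maps)
  all_vox <- threshold_fwe(grp, alpha = 1, none = TRUE)
  expect_equal(sum(attr(all_vox, "mask")), prod(shape))
  expect_error(threshold_fwe(grp, alpha = 2), "parameter error")
})

test_that("sign-flip permutation FWE is no stricter than Bonferroni here", {
  set.seed(6)
  shape <- c(5, 5, 4)
  signal <- array(0, shape); signal[2:3, 2:3, 2] <- 1.2
  maps <- lapply(1:14, function(i)
    vol_img(signal + array(rnorm(prod(shape), 0, 1), shape)))
  grp <- group_onesample_t(maps)
  bon <- threshold_fwe(grp, alpha = 0.05, method = "bonferroni")
  set.seed(99)
  perm <- threshold_fwe(grp, alpha = 0.05, method = "permutation",
                        maps = maps, n_perm = 500)
  bon_mask <- attr(bon, "mask")
  perm_mask <- attr(perm, "mask")
  expect_true(all(perm_mask[bon_mask]))
  expect_error(threshold_fwe(grp, method = "permutation"), "requires")
})

test_that("clusters use 26-connectivity and report peaks in mm", {
  shape <- c(6, 6, 6)
  tt <- array(0, shape)
  tt[2, 2, 2] <- 8; tt[3, 3, 3] <- 9           # diagonal touch: one cluster
  tt[6, 6, 6] <- 7                              # separate cluster
  maps <- lapply(1:6, function(i) vol_img(tt + array(rnorm(prod(shape), 0, 1e-3), shape)))
  grp <- group_onesample_t(maps)
  cl <- threshold_fwe(grp, alpha = 0.05, method = "bonferroni")
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$size, c(2, 1))
  big <- cl[cl$size == 2, ]
  ref <- maps[[1]]
  allowed <- rbind(as.numeric(vox_to_mm(ref, c(1, 1, 1))),
                   as.numeric(vox_to_mm(ref, c(2, 2, 2))))
  expect_true(any(apply(allowed, 1, function(mm)
    isTRUE(all.equal(mm, c(big$peak_x, big$peak_y, big$peak_z))))))
})

test_that("cluster means equal brute-force averages", {
  set.seed(9)
  shape <- c(6, 6, 6)
  base <- array(0, shape); base[2:3, 2, 2] <- 5
  maps <- lapply(1:8, function(i)
    vol_img(base + array(rnorm(prod(shape), 0, 0.1), shape)))
  names(maps) <- paste0("s", 1:8)
  grp <- group_onesample_t(maps)
  cl <- threshold_fwe(grp, alpha = 0.05)
  expect_gte(nrow(cl), 1)
  feats <- extract_cluster_means(cl, maps)
  labels <- attr(cl, "labels")
  vox <- which(labels == cl$label[1])
  brute <- vapply(maps, function(m) mean(m$data[vox]), numeric(1))
  expect_equal(unname(feats[, 1]), unname(brute))
  # single-voxel cluster returns that voxel's value; uniform map the constant
  if (any(cl$size == 1)) {
    lb <- cl$label[cl$size == 1][1]
    v1 <- which(labels == lb)
    expect_equal(unname(feats[, paste0("cluster_", lb)]),
                 vapply(maps, function(m) m$data[v1], numeric(1)),
                 ignore_attr = TRUE)
  }
  uni <- lapply(1:8, function(i) vol_img(array(2.5, shape)))
  expect_true(all(extract_cluster_means(cl, uni) == 2.5))
})

test_that("Fisher z maps negate when the seed region is negated", {
  img <- make_rest_img(10)
  center <- vox_to_mm(img, c(3, 3, 3))
  z1 <- seed_correlation_map(img, center, radius_mm = 1)
  img2 <- img
  img2$data[4, 4, 4, ] <- -img2$data[4, 4, 4, ]   # the single seed voxel
  z2 <- seed_correlation_map(img2, center, radius_mm = 1)
  off_seed <- array(TRUE, dim(z1$data)); off_seed[4, 4, 4] <- FALSE
  expect_equal(z2$data[off_seed], -z1$data[off_seed], tolerance = 1e-10)
})
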