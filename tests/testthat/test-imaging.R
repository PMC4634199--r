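test_that("vol_img validates its inputs and round-trips through NIfTI", {
  expect_error(vol_img(matrix(1, 2, 2)), "3D or 4D")
  expect_error(vol_img(array(1, c(2, 2, 2)), diag(3)), "4x4")
  img <- vol_img(array(rnorm(4 * 5 * 6), c(4, 5, 6)), ras_affine(c(4, 5, 6), 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_vol_img(img, path)
  back <- read_vol_img(path)
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_equal(back$affine, img$affine, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("voxel/mm conversions invert each other", {
  img <- vol_img(array(0, c(6, 7, 8)), ras_affine(c(6, 7, 8), 2.5))
  ijk <- rbind(c(0, 0, 0), c(5, 6, 7), c(2, 3, 4))
  expect_equal(mm_to_vox(img, vox_to_mm(img, ijk)), ijk,
               ignore_attr = TRUE)
})

test_that("smoothing with fwhm 0 is the identity and preserves constants", {
  img <- vol_img(array(rnorm(1000), c(10, 10, 10)))
  expect_identical(smooth_img(img, 0), img)
  const <- vol_img(array(3.7, c(10, 10, 10)))
  sm <- smooth_img(const, 6)
  interior <- sm$data[4:7, 4:7, 4:7]   # beyond the kernel radius
  expect_equal(interior, array(3.7, dim(interior)), tolerance = 1e-10)
})

test_that("an interior impulse smooths to the analytic Gaussian", {
  shape <- c(11, 11, 11)
  img <- vol_img(array(0, shape), ras_affine(shape, 3))
  img$data[6, 6, 6] <- 1
  sm <- smooth_img(img, 6)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3   # voxels
  r <- max(1, ceiling(4 * sigma))
  k <- dnorm(-r:r, 0, sigma); k <- k / sum(k)
  expect_true(sum(img$data) > 0)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 1, 1))) {
    expected <- prod(k[off + r + 1])
    expect_equal(sm$data[6 + off[1], 6 + off[2], 6 + off[3]], expected,
                 tolerance = 1e-6)
  }
  # total intensity conserved away from boundaries
  expect_equal(sum(sm$data), 1, tolerance = 1e-3)
})

test_that("smoothing is linear, framewise for 4D, and rejects shear", {
  shape <- c(8, 8, 8)
  a <- array(rnorm(prod(shape)), shape)
  b <- array(rnorm(prod(shape)), shape)
  s_ab <- smooth_img(vol_img(a + 2 * b), 5)$data
  s_sep <- smooth_img(vol_img(a), 5)$data + 2 * smooth_img(vol_img(b), 5)$data
  expect_equal(s_ab, s_sep, tolerance = 1e-12)
  four <- vol_img(array(c(a, b), c(shape, 2)))
  s4 <- smooth_img(four, 5)
  expect_equal(s4$data[, , , 1], smooth_img(vol_img(a), 5)$data)
  expect_equal(s4$data[, , , 2], smooth_img(vol_img(b), 5)$data)
  aff <- ras_affine(shape, 3)
  aff[1, 2] <- 1.5   # shear
  expect_error(smooth_img(vol_img(a, aff), 6), "unsupported-geometry")
})

test_that("sphere extraction matches a brute-force distance scan", {
  set.seed(42)
  for (vs in c(2, 3, 4)) {
    shape <- c(9, 10, 11)
    img <- vol_img(array(rnorm(prod(shape) * 5), c(shape, 5)),
                   ras_affine(shape, vs))
    center <- vox_to_mm(img, c(4, 5, 5)) + runif(3, -1, 1)
    radius <- vs * 1.7
    got <- extract_sphere(img, center, radius)
    mm <- vox_to_mm(img, as.matrix(expand.grid(0:(shape[1] - 1),
                                               0:(shape[2] - 1),
                                               0:(shape[3] - 1))))
    inside <- which(sqrt(colSums((t(mm) - as.numeric(center))^2)) <= radius)
    expect_setequal(got$voxels, inside)
    Y <- matrix(img$data, prod(shape), 5)
    expect_equal(got$series, colMeans(Y[inside, , drop = FALSE]))
  }
})

test_that("a 4 mm sphere on a 4 mm grid is the 7-voxel face neighbourhood", {
  shape <- c(9, 9, 9)
  img <- vol_img(array(rnorm(prod(shape)), shape), ras_affine(shape, 4))
  center <- vox_to_mm(img, c(4, 4, 4))
  got <- extract_sphere(img, center, 4)
  expect_equal(got$n_voxels, 7)
  # tiny radius centred on a voxel: that voxel's own value
  one <- extract_sphere(img, center, 1.5)
  expect_equal(one$n_voxels, 1)
  expect_equal(one$series, img$data[5, 5, 5])
  expect_error(extract_sphere(img, c(300, 0, 0), 4), "field of view")
})

test_that("first-level GLM recovers noiseless coefficients exactly", {
  set.seed(7)
  shape <- c(5, 5, 4)
  n_vol <- 40L
  X <- task_design(onsets = c(0, 30, 60), durations = 12,
                   conditions = c("two_back", "one_back", "two_back"),
                   tr_s = 3, n_volumes = n_vol - 4L)
  V <- prod(shape)
  b <- matrix(rnorm(ncol(X) * V), ncol(X), V,
              dimnames = list(colnames(X), NULL))
  Y <- X %*% b
  arr <- array(0, c(shape, n_vol))
  full <- rbind(matrix(rnorm(4 * V), 4, V), Y)  # first 4 frames discarded
  for (t in seq_len(n_vol)) arr[, , , t] <- array(full[t, ], shape)
  img <- vol_img(arr)
  cw <- setNames(numeric(ncol(X)), colnames(X))
  cw["two_back"] <- 1; cw["one_back"] <- -1
  con <- first_level_glm(img, X, cw, drop_initial = 4)
  truth <- as.numeric(b["two_back", ] - b["one_back", ])
  expect_equal(as.numeric(con$data), truth, tolerance = 1e-8)
})

test_that("GLM betas equal the pseudoinverse oracle and ignore modelled motion", {
  set.seed(8)
  shape <- c(4, 4, 3)
  n_vol <- 44L
  motion <- matrix(rnorm(6 * (n_vol - 4)), ncol = 6)
  X <- task_design(onsets = c(6, 48, 90), durations = 15,
                   conditions = c("a", "b", "a"), tr_s = 3,
                   n_volumes = n_vol - 4L, motion = motion)
  V <- prod(shape)
  noise <- matrix(rnorm((n_vol - 4) * V), n_vol - 4, V)
  arr <- array(0, c(shape, n_vol))
  for (t in 5:n_vol) arr[, , , t] <- array(noise[t - 4, ], shape)
  img <- vol_img(arr)
  con <- first_level_glm(img, X, c(a = 1, b = -1))
  oracle <- apply(noise, 2, function(y) {
    bb <- pinv_lm(X, y)
    bb[1] - bb[2]
  })
  expect_equal(as.numeric(con$data), oracle, tolerance = 1e-8)
  # adding scaled motion into the data leaves the task contrast unchanged
  leak <- noise + as.numeric(motion %*% rnorm(6, 0, 3))
  arr2 <- arr
  for (t in 5:n_vol) arr2[, , , t] <- array(leak[t - 4, ], shape)
  con2 <- first_level_glm(vol_img(arr2), X, c(a = 1, b = -1))
  expect_equal(con2$data, con$data, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  X <- task_design(onsets = c(0, 30), durations = 12,
                   conditions = c("a", "b"), tr_s = 3, n_volumes = 30)
  X <- cbind(X, dup = X[, "a"])
  img <- vol_img(array(rnorm(2 * 2 * 2 * 34), c(2, 2, 2, 34)))
  expect_error(first_level_glm(img, X, c(a = 1)), "collinear.*dup|dup.*collinear")
})

test_that("design construction validates timing and motion shape", {
  expect_error(task_design(onsets = 100, durations = 50, conditions = "a",
                           tr_s = 3, n_volumes = 40), "exceed")
  expect_error(task_design(onsets = 0, durations = 10, conditions = "a",
                           tr_s = 3, n_volumes = 40,
                           motion = matrix(0, 40, 5)), "6 motion")
  h <- hrf_double_gamma(seq(0, 32, 0.5))
  expect_equal(max(h), 1, tolerance = 1e-3)
  expect_equal(which.max(h), which.min(abs(seq(0, 32, 0.5) - 5)))
  expect_lt(min(h), 0)  # undershoot
})
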