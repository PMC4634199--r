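#' Volumetric image with a voxel-to-mm affine
#'
#' A lightweight container for 3D (space) or 4D (space x time) intensity
#' grids together with a 4x4 affine mapping 0-based voxel indices to mm
#' coordinates (RAS convention). The time axis of a 4D image is last.
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param affine 4x4 invertible matrix; column i scales voxel axis i.
#' @return an object of class `vol_img` with elements `data` and `affine`.
#' @export
vol_img <- function(data, affine = ras_affine(dim(data)[1:3])) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("vol_img: data must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("vol_img: affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("vol_img: affine must be invertible")
  structure(list(data = data, affine = affine), class = "vol_img")
}

#' Default RAS affine for an image grid
#'
#' Isotropic voxels of size `voxel_size_mm`, grid centred on the mm origin.
#'
#' @param shape integer 3-vector of spatial dimensions.
#' @param voxel_size_mm voxel edge length in mm.
#' @return 4x4 affine matrix.
#' @export
ras_affine <- function(shape, voxel_size_mm = 4) {
  shape <- as.integer(shape[1:3])
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a[1:3, 4] <- -(shape - 1) / 2 * voxel_size_mm
  a
}

#' @export
print.vol_img <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol_img> %s voxels, voxel size %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(voxel_sizes(x$affine), 3), collapse = " x ")))
  invisible(x)
}

is_vol_img <- function(x) inherits(x, "vol_img")

spatial_dim <- function(img) dim(img$data)[1:3]

n_volumes <- function(img) {
  d <- dim(img$data)
  if (length(d) == 4L) d[4] else 1L
}

#' Voxel edge lengths implied by an affine
#' @param affine 4x4 affine matrix.
#' @return numeric 3-vector of mm per voxel along each axis.
#' @export
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# error if the spatial axes are not mutually orthogonal (sheared affine)
check_no_shear <- function(affine) {
  R <- affine[1:3, 1:3]
  Rn <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  G <- crossprod(Rn)
  if (max(abs(G - diag(3))) > 1e-6)
    stop("unsupported-geometry: affine has shear (non-orthogonal axes)")
  invisible(TRUE)
}

#' Convert 0-based voxel indices to mm coordinates
#' @param img a `vol_img`.
#' @param ijk matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
vox_to_mm <- function(img, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(img$affine[1:3, 1:3] %*% t(ijk) + img$affine[1:3, 4])
}

#' Convert mm coordinates to 0-based voxel indices (real-valued)
#' @param img a `vol_img`.
#' @param xyz matrix (n x 3) or vector of mm coordinates.
#' @return n x 3 matrix of real-valued 0-based voxel indices.
#' @export
mm_to_vox <- function(img, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  A <- solve(img$affine)
  t(A[1:3, 1:3] %*% t(xyz) + A[1:3, 4])
}

# mm coordinates of every voxel centre, as a V x 3 matrix (column-major order)
voxel_grid_mm <- function(img) {
  d <- spatial_dim(img)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  vox_to_mm(img, ijk)
}

#' Write a volumetric image as NIfTI-1
#' @param img a `vol_img`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_vol_img <- function(img, path) {
  stopifnot(is_vol_img(img))
  ni <- RNifti::asNifti(img$data)
  RNifti::pixdim(ni) <- voxel_sizes(img$affine)
  RNifti::sform(ni) <- structure(img$affine, code = 2L)
  RNifti::qform(ni) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a `vol_img`
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return a `vol_img`.
#' @export
read_vol_img <- function(path) {
  ni <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(ni)), 4, 4)
  vol_img(array(as.numeric(ni), dim(ni)), aff)
}

#' Discard initial volumes of a 4D series
#'
#' Drops the leading frames of a time series (steady-state dummy scans).
#'
#' @param img a 4D `vol_img`.
#' @param n number of initial volumes to discard (default 4).
#' @return a 4D `vol_img` with `n` fewer volumes.
#' @export
drop_initial_volumes <- function(img, n = 4L) {
  stopifnot(is_vol_img(img), length(dim(img$data)) == 4L)
  TT <- dim(img$data)[4]
  if (n >= TT) stop("drop_initial_volumes: would remove every volume")
  if (n == 0L) return(img)
  vol_img(img$data[, , , (n + 1):TT, drop = FALSE], img$affine)
}

# convolve along the first array axis with a banded kernel matrix
conv_axis1 <- function(m, kernel) {
  n <- nrow(m)
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    keep <- idx + o >= 1 & idx + o <= n
    C[cbind(idx[keep], (idx + o)[keep])] <- kernel[o + r + 1L]
  }
  C %*% m
}

smooth_frame <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, 0, s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- matrix(a, nrow = dm[1])
    a <- conv_axis1(a, k)
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Spatial Gaussian smoothing
#'
#' Smooths a 3D image (or each frame of a 4D series) with a separable
#' Gaussian kernel of the given full width at half maximum in mm. The
#' per-axis sigma in voxels is `fwhm / (2 sqrt(2 log 2))` divided by the
#' voxel size taken from the affine. Kernels are normalised to unit sum, so
#' the total intensity of a nonnegative image is conserved away from the
#' grid boundary (zero padding outside).
#'
#' @param img a 3D or 4D `vol_img` with an orthogonal (shear-free) affine.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is the identity.
#' @return a smoothed `vol_img` in the same geometry.
#' @export
smooth_img <- function(img, fwhm_mm) {
  stopifnot(is_vol_img(img), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(img)
  check_no_shear(img$affine)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_sizes(img$affine)
  d <- dim(img$data)
  if (length(d) == 3L) {
    out <- smooth_frame(img$data, sigma_vox)
  } else {
    out <- img$data
    for (t in seq_len(d[4])) out[, , , t] <- smooth_frame(img$data[, , , t], sigma_vox)
  }
  vol_img(out, img$affine)
}

#' Mean time series within a sphere at a mm coordinate
#'
#' The sphere contains every voxel whose centre lies within `radius_mm`
#' (Euclidean distance in mm via the affine) of `center_mm`; membership is by
#' voxel centre, without partial-volume weighting.
#'
#' @param img a 3D or 4D `vol_img`.
#' @param center_mm mm coordinate of the sphere centre (length 3).
#' @param radius_mm sphere radius in mm.
#' @return list with `series` (per-volume mean over sphere voxels; a scalar
#'   for 3D input), `n_voxels`, and `voxels` (linear spatial indices).
#' @export
extract_sphere <- function(img, center_mm, radius_mm) {
  stopifnot(is_vol_img(img), length(center_mm) == 3, radius_mm > 0)
  d <- spatial_dim(img)
  v <- mm_to_vox(img, center_mm)
  if (any(v < -0.5) || any(v > d - 0.5))
    stop("extract_sphere: center outside the field of view")
  mm <- voxel_grid_mm(img)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  vox <- which(d2 <= radius_mm^2)
  if (length(vox) == 0L)
    stop("empty-region: no voxel centre within radius of the sphere centre")
  V <- prod(d)
  if (length(dim(img$data)) == 3L) {
    series <- mean(img$data[vox])
  } else {
    TT <- dim(img$data)[4]
    m <- matrix(img$data, nrow = V, ncol = TT)
    series <- colMeans(m[vox, , drop = FALSE])
  }
  list(series = series, n_voxels = length(vox), voxels = vox)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma shape: response peaking at 6 s with a 16 s undershoot
#' of 1/6 relative amplitude, normalised to unit peak.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  tp <- seq(0, 32, by = 0.01)
  h / max(stats::dgamma(tp, shape = 6, rate = 1) -
            stats::dgamma(tp, shape = 16, rate = 1) / 6)
}

#' Build a first-level block design matrix
#'
#' Boxcar regressors per condition convolved with the canonical double-gamma
#' HRF on an oversampled grid and sampled at volume acquisition times, plus
#' optional motion and extra nuisance columns and an intercept.
#'
#' @param onsets block onsets in seconds.
#' @param durations block durations in seconds (scalar or per-block).
#' @param conditions condition label per block.
#' @param tr_s repetition time in seconds.
#' @param n_volumes number of volumes the design covers.
#' @param motion optional matrix with exactly 6 motion columns.
#' @param nuisance optional matrix of extra nuisance regressors (e.g. the
#'   instruction screen), with named columns.
#' @param oversample temporal oversampling factor for the convolution grid.
#' @return design matrix with named columns (conditions first, intercept last).
#' @export
task_design <- function(onsets, durations, conditions, tr_s, n_volumes,
                        motion = NULL, nuisance = NULL, oversample = 16L) {
  stopifnot(tr_s > 0, n_volumes >= 1, length(onsets) == length(conditions))
  durations <- rep_len(durations, length(onsets))
  scan_dur <- n_volumes * tr_s
  if (any(onsets < 0) || any(onsets + durations > scan_dur))
    stop("task_design: onsets + durations exceed scan duration")
  dt <- tr_s / oversample
  tg <- seq(0, scan_dur, by = dt)
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  labs <- unique(conditions)
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  X <- sapply(labs, function(lb) {
    box <- numeric(length(tg))
    for (b in which(conditions == lb))
      box[tg >= onsets[b] & tg < onsets[b] + durations[b]] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tg)]
    stats::approx(tg, conv, xout = vol_t, rule = 2)$y
  })
  colnames(X) <- labs
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stop("task_design: exactly 6 motion columns required")
    if (nrow(motion) != n_volumes) stop("task_design: motion rows must equal n_volumes")
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes) stop("task_design: nuisance rows must equal n_volumes")
    X <- cbind(X, nuisance)
  }
  cbind(X, intercept = 1)
}

#' Simplified first-level GLM producing a contrast image
#'
#' Discards the first `drop_initial` volumes (steady-state scans), fits
#' per-voxel ordinary least squares against the design matrix, and returns
#' the weighted coefficient combination as a 3D contrast map. Temporal
#' autocorrelation is not modelled.
#'
#' @param img4d a 4D `vol_img`.
#' @param design design matrix whose rows match the retained volumes
#'   (i.e. `n_volumes - drop_initial`), e.g. from [task_design()].
#' @param contrast_weights numeric contrast vector, either full length or a
#'   named vector matched against design columns (unnamed columns weight 0).
#' @param drop_initial number of leading volumes to discard (default 4).
#' @return a 3D `vol_img` contrast map; attributes `beta` (coefficients x
#'   voxels) and `design_cols`.
#' @export
first_level_glm <- function(img4d, design, contrast_weights, drop_initial = 4L) {
  stopifnot(is_vol_img(img4d), length(dim(img4d$data)) == 4L)
  img <- drop_initial_volumes(img4d, drop_initial)
  X <- as.matrix(design)
  TT <- dim(img$data)[4]
  if (nrow(X) != TT)
    stop("first_level_glm: design rows must equal retained volumes")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("first_level_glm: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cw <- expand_contrast(contrast_weights, colnames(X))
  d <- spatial_dim(img)
  Y <- matrix(img$data, nrow = prod(d), ncol = TT)
  beta <- qr.coef(qx, t(Y))            # p x V
  con <- as.numeric(cw %*% beta)
  out <- vol_img(array(con, dim = d), img$affine)
  attr(out, "beta") <- beta
  attr(out, "design_cols") <- colnames(X)
  out
}

expand_contrast <- function(w, cols) {
  if (!is.null(names(w)) && any(nzchar(names(w)))) {
    miss <- setdiff(names(w), cols)
    if (length(miss)) stop("contrast names not in design: ",
                           paste(miss, collapse = ", "))
    full <- stats::setNames(numeric(length(cols)), cols)
    full[names(w)] <- w
    matrix(full, nrow = 1)
  } else {
    if (length(w) != length(cols))
      stop("contrast length must match design columns")
    matrix(as.numeric(w), nrow = 1)
  }
}
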