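# Fisher-z ceiling for (partial) correlations; |r| is clamped to tanh(Z_CAP)
# before the transform so self-correlated voxels map to a finite value.
Z_CAP <- 10

#' Seed-based connectivity map with nuisance regression
#'
#' Extracts the mean seed time series from a sphere, residualises both the
#' seed and every voxel series against the nuisance set (plus intercept),
#' and maps the Fisher z of the resulting partial correlation at every
#' voxel. Values are capped at |z| = 10 (the documented ceiling, reached
#' only for numerically perfect correlations).
#'
#' @param img4d a 4D `vol_img` (steady-state volumes already discarded).
#' @param seed_center_mm mm coordinate of the seed.
#' @param nuisance data.frame/matrix of nuisance series (WM, CSF, six motion
#'   columns), or `NULL`; rows must match the retained volumes.
#' @param radius_mm seed sphere radius in mm (default 4).
#' @return a 3D `vol_img` of Fisher-z values; attribute `seed_series`.
#' @export
seed_correlation_map <- function(img4d, seed_center_mm, nuisance = NULL,
                                 radius_mm = 4) {
  stopifnot(is_vol_img(img4d), length(dim(img4d$data)) == 4L)
  TT <- dim(img4d$data)[4]
  if (TT < 20L) stop("seed_correlation_map: at least 20 retained volumes required")
  sph <- extract_sphere(img4d, seed_center_mm, radius_mm)
  seed <- sph$series
  N <- matrix(1, TT, 1)
  if (!is.null(nuisance)) {
    nm <- as.matrix(nuisance)
    if (nrow(nm) != TT)
      stop("seed_correlation_map: nuisance rows must match volumes")
    N <- cbind(N, nm)
    fit <- stats::lm.fit(N, seed)
    r2 <- 1 - sum(fit$residuals^2) / sum((seed - mean(seed))^2)
    if (r2 > 0.999^2)
      stop("degenerate-nuisance: nuisance set is collinear with the seed series")
  }
  qn <- qr(N)
  rs <- qr.resid(qn, seed)
  d <- spatial_dim(img4d)
  Y <- matrix(img4d$data, nrow = prod(d), ncol = TT)
  RY <- t(qr.resid(qn, t(Y)))
  num <- RY %*% rs
  ss_res <- rowSums(RY^2)
  den <- sqrt(ss_res) * sqrt(sum(rs^2))
  r <- as.numeric(num) / den
  # voxels whose series lie (numerically) in the nuisance span carry no
  # signal of their own: define their partial correlation as 0
  ss_tot <- rowSums((Y - rowMeans(Y))^2)
  r[!is.finite(r) | ss_res <= 1e-12 * pmax(ss_tot, .Machine$double.eps)] <- 0
  r <- pmin(pmax(r, -tanh(Z_CAP)), tanh(Z_CAP))
  vol_img(array(atanh(r), dim = d), img4d$affine)
}

# cap for one-sample t statistics where the sample variance is exactly zero
T_CAP <- 1e6

#' Group one-sample t-test over subject maps
#'
#' Per-voxel one-tailed (positive) one-sample t of Fisher-z values against
#' zero with `n - 1` degrees of freedom. Voxels with zero sample variance
#' and nonzero mean are capped at t = 1e6 (p = 0).
#'
#' @param maps list of 3D `vol_img` in identical geometry (one per subject).
#' @param mask optional logical array (or `vol_img`); voxels outside get NA.
#' @return list with `t` and `p` (`vol_img`), `n`, `df`, and `mask` array.
#' @export
group_onesample_t <- function(maps, mask = NULL) {
  stopifnot(is.list(maps), length(maps) >= 3)
  aff <- maps[[1]]$affine
  d <- spatial_dim(maps[[1]])
  for (m in maps)
    if (!isTRUE(all.equal(m$affine, aff)) || !identical(spatial_dim(m), d))
      stop("geometry error: subject maps have mismatched affines or shapes")
  mk <- mask_array(mask, d)
  X <- vapply(maps, function(m) as.numeric(m$data), numeric(prod(d)))
  n <- length(maps)
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (n - 1))
  tt <- mu / (s / sqrt(n))
  tt[s == 0 & mu == 0] <- 0
  tt[!is.finite(tt)] <- sign(mu[!is.finite(tt)]) * T_CAP
  tt <- pmin(pmax(tt, -T_CAP), T_CAP)
  p <- stats::pt(tt, df = n - 1, lower.tail = FALSE)
  tt[!mk] <- NA_real_
  p[!mk] <- NA_real_
  list(t = vol_img(array(tt, dim = d), aff),
       p = vol_img(array(p, dim = d), aff),
       n = n, df = n - 1, mask = mk)
}

mask_array <- function(mask, d) {
  if (is.null(mask)) return(array(TRUE, dim = d))
  if (is_vol_img(mask)) mask <- mask$data
  mk <- array(as.logical(mask != 0 & !is.na(mask)), dim = d)
  mk[is.na(mk)] <- FALSE
  mk
}

#' Family-wise-error thresholding and cluster extraction
#'
#' Thresholds a group one-sample t map at FWE level `alpha`. The default
#' method is Bonferroni over in-mask voxels (deterministic); the permutation
#' method uses the sign-flip max-statistic distribution and requires the
#' subject maps. Surviving voxels are grouped into clusters by
#' 26-connectivity.
#'
#' @param group result of [group_onesample_t()].
#' @param alpha FWE level in (0, 1).
#' @param method "bonferroni" or "permutation".
#' @param maps subject maps (required for `method = "permutation"`).
#' @param n_perm number of sign-flip permutations.
#' @param min_cluster minimum cluster size in voxels (default 1).
#' @param none if `TRUE`, no correction: threshold at uncorrected `alpha`.
#' @return object of class `cluster_set`: data.frame of clusters (label,
#'   size, peak mm coordinates, peak t) with attributes `labels` (label
#'   array) and `mask` (surviving-voxel array).
#' @export
threshold_fwe <- function(group, alpha = 0.05,
                          method = c("bonferroni", "permutation"),
                          maps = NULL, n_perm = 1000L, min_cluster = 1L,
                          none = FALSE) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("parameter error: alpha must be in (0,1]")
  mk <- group$mask
  V <- sum(mk)
  if (V < 1) stop("threshold_fwe: empty mask")
  tt <- group$t$data
  if (none) {
    surv <- mk & !is.na(group$p$data) & group$p$data <= alpha
  } else if (method == "bonferroni") {
    surv <- mk & !is.na(group$p$data) & group$p$data <= alpha / V
  } else {
    if (is.null(maps)) stop("permutation FWE requires the subject maps")
    X <- vapply(maps, function(m) as.numeric(m$data), numeric(length(mk)))
    X <- X[as.logical(mk), , drop = FALSE]
    n <- ncol(X)
    maxt <- vapply(seq_len(n_perm), function(b) {
      sg <- sample(c(-1, 1), n, replace = TRUE)
      Xs <- sweep(X, 2, sg, "*")
      mu <- rowMeans(Xs)
      s <- sqrt(rowSums((Xs - mu)^2) / (n - 1))
      tb <- mu / (s / sqrt(n))
      max(tb[is.finite(tb)])
    }, numeric(1))
    crit <- stats::quantile(maxt, 1 - alpha, names = FALSE, type = 1)
    surv <- mk & !is.na(tt) & tt >= crit
  }
  cl <- label_clusters(surv, connectivity = 26L)
  build_cluster_set(cl, tt, group$t$affine, min_cluster, surv)
}

build_cluster_set <- function(labels, tmap, affine, min_cluster, surv) {
  d <- dim(labels)
  labs <- sort(unique(labels[labels > 0]))
  rows <- list()
  keep <- array(0L, dim = d)
  new_lab <- 0L
  ref <- vol_img(array(0, dim = d), affine)
  for (lb in labs) {
    vox <- which(labels == lb)
    if (length(vox) < min_cluster) next
    new_lab <- new_lab + 1L
    keep[vox] <- new_lab
    pk <- vox[which.max(tmap[vox])]
    ijk <- arrayInd(pk, d) - 1L
    mm <- vox_to_mm(ref, ijk)
    rows[[new_lab]] <- data.frame(label = new_lab, size = length(vox),
                                  peak_x = mm[1], peak_y = mm[2],
                                  peak_z = mm[3],
                                  peak_t = tmap[pk])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), size = integer(), peak_x = numeric(),
               peak_y = numeric(), peak_z = numeric(), peak_t = numeric())
  structure(out, labels = keep, mask = keep > 0, affine = affine,
            class = c("cluster_set", "data.frame"))
}

# connected-component labelling of a logical 3D array (26- or 6-connectivity)
label_clusters <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Per-subject mean map value within each cluster
#'
#' The scalar fMRI feature entering the compensation model: the mean of a
#' subject's map over the voxels of each cluster.
#'
#' @param cluster_set a `cluster_set` from [threshold_fwe()].
#' @param maps list of subject `vol_img` in the cluster geometry.
#' @return matrix (subjects x clusters), column names `cluster_<label>`.
#' @export
extract_cluster_means <- function(cluster_set, maps) {
  labels <- attr(cluster_set, "labels")
  if (nrow(cluster_set) == 0) stop("extract_cluster_means: empty cluster set")
  out <- sapply(cluster_set$label, function(lb) {
    vox <- which(labels == lb)
    if (!length(vox)) stop("extract_cluster_means: empty cluster")
    vapply(maps, function(m) mean(m$data[vox]), numeric(1))
  })
  out <- matrix(out, nrow = length(maps))
  colnames(out) <- paste0("cluster_", cluster_set$label)
  rownames(out) <- names(maps)
  out
}
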