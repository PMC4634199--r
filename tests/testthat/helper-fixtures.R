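# small, fast fixtures shared across test files

small_spec <- function(...) {
  cohort_spec(n_carriers = 40L, n_controls = 20L, n_sites = 2L,
              image_shape = c(12L, 14L, 12L), voxel_size_mm = 4,
              n_volumes_rest = 60L, ...)
}

small_truth <- function(seed = 123L, ...) {
  ground_truth(effect_coords = list(c(8, -8, 8), c(-12, 12, -8)),
               rest_seed_mm = c(12, 12, 8), rest_target_mm = c(-12, -12, -8),
               seed = seed, ...)
}

# independent per-voxel OLS via SVD pseudoinverse (oracle for GLM paths)
pinv_lm <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  beta <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  as.numeric(beta)
}

# full oracle: coefficient, t and two-sided p for one column of X
pinv_fit <- function(X, y, col) {
  beta <- pinv_lm(X, y)
  res <- y - X %*% beta
  dfres <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dfres
  XtXinv <- solve(crossprod(X))
  se <- sqrt(s2 * XtXinv[col, col])
  tval <- beta[col] / se
  list(beta = beta[col], t = tval,
       p = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE))
}

# design matrix matching the compensation model used by the package
comp_design <- function(records, f, disease_load) {
  d <- records[[disease_load]]
  mm <- stats::model.matrix(
    ~ d + age + factor(gender) + factor(site) + education + cpo,
    data.frame(d = d, records))
  cbind(mm, f = f, d_f = d * f)
}
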