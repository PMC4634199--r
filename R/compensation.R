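#' Fit the compensation model for one feature and one disease load
#'
#' Ordinary least squares for
#' `y = alpha + beta1 d + beta2 f + beta3 d f + gamma c + e`, where `d` is a
#' regional volume as a fraction of intracranial volume (raw scale; smaller
#' volume = higher structural disease load), `f` a scalar fMRI feature, and
#' the covariates default to age, gender, site, education and CPO.
#' Evidence for an activity-by-load modulation is the test of
#' `H0: beta3 = 0`; the nominal criterion is p <= 0.05 without
#' multiplicity adjustment (a pre-planned Bonferroni correction across the
#' four disease-load measures is applied separately, see
#' [bonferroni_disease_load()]). Complete cases only.
#'
#' @param records data.frame of subjects (typically the gene-carrier rows).
#' @param f numeric feature vector (length `nrow(records)`) or the name of a
#'   column of `records`.
#' @param disease_load name of the volume-fraction column (`"caudate"`,
#'   `"putamen"`, `"gray"`, `"white"`).
#' @param y name of the performance column.
#' @param covariates covariate column names; character columns enter as
#'   factors (reference level = first alphabetically).
#' @param factor_covariates covariates coerced to factors even when stored
#'   numerically (default gender and study site).
#' @param alternative sidedness of the beta3 test (default two-sided).
#' @param kappa_max condition-number threshold for the collinearity
#'   diagnostic (on column-normalised design).
#' @return object of class `compensation_fit`: coefficients, standard
#'   errors, `t`/`p` for beta3, residual sd, n, names.
#' @export
fit_compensation <- function(records, f, disease_load = "caudate",
                             y = "dprime_2back",
                             covariates = c("age", "gender", "site",
                                            "education", "cpo"),
                             alternative = c("two.sided", "greater", "less"),
                             factor_covariates = c("gender", "site"),
                             kappa_max = 1e10) {
  alternative <- match.arg(alternative)
  feature_name <- if (is.character(f) && length(f) == 1) f else "feature"
  fv <- if (is.character(f) && length(f) == 1) records[[f]] else as.numeric(f)
  stopifnot(length(fv) == nrow(records))
  df <- data.frame(y = records[[y]], d = records[[disease_load]], f = fv)
  covariates <- covariates[covariates %in% names(records)]
  for (cv in covariates) {
    col <- records[[cv]]
    if (is.character(col) || is.factor(col) || cv %in% factor_covariates) {
      col <- factor(col)
      if (nlevels(droplevels(col[stats::complete.cases(df)])) < 2) next
    }
    df[[cv]] <- col
  }
  used_cov <- setdiff(names(df), c("y", "d", "f"))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  for (cv in used_cov) {
    if (is.factor(df[[cv]])) df[[cv]] <- droplevels(df[[cv]])
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  }
  fml <- stats::as.formula(paste(c("y ~ d * f", used_cov), collapse = " + "))
  X <- stats::model.matrix(fml, df)
  if (nrow(X) < ncol(X) + 10)
    stop("fit_compensation: need at least ", ncol(X) + 10, " complete cases")
  Xn <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  kp <- kappa(Xn, exact = TRUE)
  if (kp > kappa_max) {
    sv <- svd(Xn)
    w <- abs(sv$v[, ncol(Xn)])
    bad <- colnames(X)[w > 0.3]
    stop("collinearity: condition number ", format(kp, digits = 3),
         "; offending columns: ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  b3 <- co["d:f", ]
  dfres <- fit$df.residual
  p <- switch(alternative,
              two.sided = b3["Pr(>|t|)"],
              greater = stats::pt(b3["t value"], dfres, lower.tail = FALSE),
              less = stats::pt(b3["t value"], dfres))
  structure(list(alpha = unname(co["(Intercept)", "Estimate"]),
                 beta1 = unname(co["d", "Estimate"]),
                 beta2 = unname(co["f", "Estimate"]),
                 beta3 = unname(b3["Estimate"]),
                 gamma = co[setdiff(rownames(co),
                                    c("(Intercept)", "d", "f", "d:f")),
                            "Estimate"],
                 se = stats::setNames(co[, "Std. Error"], rownames(co)),
                 t = unname(b3["t value"]),
                 p = unname(p),
                 sigma = sm$sigma, n = nrow(df), df_residual = dfres,
                 disease_load = disease_load, feature = feature_name,
                 y = y, alternative = alternative,
                 coefficients = co, model = fit),
            class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf("Compensation model: %s ~ %s x %s (n = %d)\n", x$y,
              x$disease_load, x$feature, x$n))
  cat(sprintf("  beta3 = %.4g (SE %.3g), t(%d) = %.3f, p = %.4g [%s]\n",
              x$beta3, x$se["d:f"], x$df_residual, x$t, x$p, x$alternative))
  invisible(x)
}

#' Voxelwise compensation mapping within a mask
#'
#' Applies the compensation model independently at every in-mask voxel of
#' the subjects' contrast images, taking each voxel's contrast value as the
#' fMRI feature `f`. Returns t and p maps for the interaction coefficient
#' beta3 in the input geometry; voxels at `p < p_report` (default 0.001
#' uncorrected, two-sided) are tabulated.
#'
#' @param images list of 3D `vol_img`, one per row of `records` (same order).
#' @param mask logical array / `vol_img` of in-mask voxels (typically the
#'   FWE-thresholded task main effect).
#' @param records subject table (typically carriers only).
#' @param disease_load volume-fraction column name.
#' @param y performance column name.
#' @param covariates covariate column names (as in [fit_compensation()]).
#' @param p_report uncorrected reporting threshold for the voxel table.
#' @return list with `t`, `p`, `beta3` (`vol_img`), `df`, `n`, `mask`, and
#'   `voxels` (data.frame of voxels below `p_report`: mm peak coordinates,
#'   beta3, t, p).
#' @export
voxelwise_compensation <- function(images, mask, records,
                                   disease_load = "caudate",
                                   y = "dprime_2back",
                                   covariates = c("age", "gender", "site",
                                                  "education", "cpo"),
                                   p_report = 0.001) {
  stopifnot(is.list(images), length(images) == nrow(records))
  d <- spatial_dim(images[[1]])
  aff <- images[[1]]$affine
  mk <- mask_array(mask, d)
  vox <- which(mk)
  if (!length(vox)) stop("voxelwise_compensation: empty mask")
  F <- vapply(images, function(m) as.numeric(m$data)[vox],
              numeric(length(vox)))
  F <- matrix(F, nrow = length(vox))          # voxels x subjects
  base <- compensation_design_base(records, disease_load, y, covariates)
  Xb <- base$X; yy <- base$y; dd <- base$d; keep <- base$keep
  F <- F[, keep, drop = FALSE]
  n <- length(yy)
  p_par <- ncol(Xb) + 2L
  dfres <- n - p_par
  if (dfres < 10) stop("voxelwise_compensation: too few complete cases")
  tmap <- pmap <- bmap <- array(NA_real_, dim = d)
  for (i in seq_along(vox)) {
    fv <- F[i, ]
    X <- cbind(Xb, f = fv, `d:f` = dd * fv)
    XtX <- crossprod(X)
    Xty <- crossprod(X, yy)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) next
    beta <- backsolve(ch, forwardsolve(t(ch), Xty))
    res <- yy - X %*% beta
    s2 <- sum(res^2) / dfres
    inv <- chol2inv(ch)
    j <- ncol(X)
    se3 <- sqrt(s2 * inv[j, j])
    b3 <- beta[j]
    v <- vox[i]
    bmap[v] <- b3
    tmap[v] <- b3 / se3
    pmap[v] <- 2 * stats::pt(abs(b3 / se3), dfres, lower.tail = FALSE)
  }
  sig <- which(!is.na(pmap) & pmap < p_report)
  ref <- vol_img(array(0, dim = d), aff)
  tab <- if (length(sig)) {
    mm <- vox_to_mm(ref, arrayInd(sig, d) - 1L)
    data.frame(x = mm[, 1], y = mm[, 2], z = mm[, 3],
               beta3 = bmap[sig], t = tmap[sig], p = pmap[sig])
  } else data.frame(x = numeric(), y = numeric(), z = numeric(),
                    beta3 = numeric(), t = numeric(), p = numeric())
  list(t = vol_img(tmap, aff), p = vol_img(pmap, aff),
       beta3 = vol_img(bmap, aff), df = dfres, n = n, mask = mk,
       voxels = tab[order(tab$p), ])
}

# shared design pieces for the voxelwise fits: intercept, d, covariates
compensation_design_base <- function(records, disease_load, y, covariates,
                                     factor_covariates = c("gender", "site")) {
  df <- data.frame(y = records[[y]], d = records[[disease_load]])
  covariates <- covariates[covariates %in% names(records)]
  for (cv in covariates) {
    col <- records[[cv]]
    if (is.character(col) || is.factor(col) || cv %in% factor_covariates)
      col <- factor(col)
    df[[cv]] <- col
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  for (cv in covariates)
    if (is.factor(df[[cv]])) df[[cv]] <- droplevels(df[[cv]])
  used <- covariates[vapply(covariates, function(cv)
    !is.factor(df[[cv]]) || nlevels(df[[cv]]) > 1, logical(1))]
  fml <- stats::as.formula(paste(c("~ d", used), collapse = " + "))
  X <- stats::model.matrix(fml, df)
  list(X = X, y = df$y, d = df$d, keep = keep)
}

#' Pre-planned Bonferroni correction across disease-load measures
#'
#' The family is the set of structural disease-load measures a feature was
#' tested against (default family size 4: caudate, putamen, grey, white).
#' A result is declared significant after correction iff `p <= alpha / m`.
#'
#' @param p named numeric vector of raw p-values (one per disease load).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with raw and adjusted p-values and both decisions.
#' @export
#' @examples
#' bonferroni_disease_load(c(gray = 0.010, putamen = 0.019,
#'                           caudate = 0.2, white = 0.5))
bonferroni_disease_load <- function(p, alpha = 0.05) {
  if (length(p) < 1) stop("bonferroni_disease_load: empty family")
  m <- length(p)
  data.frame(measure = if (is.null(names(p))) as.character(seq_len(m)) else names(p),
             p_raw = as.numeric(p),
             p_adjusted = pmin(1, as.numeric(p) * m),
             significant_raw = as.numeric(p) <= alpha,
             significant_adjusted = as.numeric(p) <= alpha / m,
             row.names = NULL)
}

#' Classify a fitted interaction as compensatory or not
#'
#' Evaluates the performance-activity slope `beta2 + beta3 d` at a low and a
#' high value of the volume fraction `d` (note: low volume = high structural
#' disease load). If the interaction is not significant the label is
#' `"none"`. Otherwise the pattern is `"compensatory"` when the slope at
#' high load (low `d`) exceeds the slope at low load and is positive —
#' activity buys more performance where atrophy is greater — and
#' `"non-compensatory"` when the slope at high load is smaller than at low
#' load or negative.
#'
#' @param fit a `compensation_fit`.
#' @param d_low,d_high evaluation points; default the 10th and 90th
#'   percentiles of the fitted `d` values.
#' @param alpha significance criterion for beta3 (default nominal 0.05).
#' @return list with `label`, `slope_low_d` (high load), `slope_high_d`
#'   (low load), `d_low`, `d_high`, `p`.
#' @export
classify_pattern <- function(fit, d_low = NULL, d_high = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "compensation_fit"))
  if (is.null(d_low) || is.null(d_high)) {
    dv <- fit$model$model$d
    qs <- stats::quantile(dv, c(0.1, 0.9), names = FALSE)
    if (is.null(d_low)) d_low <- qs[1]
    if (is.null(d_high)) d_high <- qs[2]
  }
  if (!(d_low < d_high)) stop("classify_pattern: d_low must be < d_high")
  s_low <- fit$beta2 + fit$beta3 * d_low     # slope at high load
  s_high <- fit$beta2 + fit$beta3 * d_high   # slope at low load
  label <- if (fit$p > alpha) "none"
  else if (s_low > s_high && s_low > 0) "compensatory"
  else "non-compensatory"
  list(label = label, slope_low_d = s_low, slope_high_d = s_high,
       d_low = d_low, d_high = d_high, p = fit$p)
}

#' Equal-count overlapping intervals for a conditioning plot
#'
#' Cleveland-style interval construction on the sorted conditioning variable
#' `d`: with target count `m = n / (k (1 - overlap) + overlap)`, interval
#' `j` spans sorted ranks `round((j-1) m (1-overlap))` through that plus
#' `ceiling(m) - 1` (0-based, clipped to the data), so that approximately
#' the same number of observations lies in each interval and approximately
#' the same number lies in two successive intervals. A least-squares line of
#' `y` on `f` is fitted within each interval for display.
#'
#' @param d conditioning variable (structural disease load).
#' @param f fMRI feature (scatterplot x-axis).
#' @param y performance (scatterplot y-axis).
#' @param k number of intervals.
#' @param overlap target shared fraction between successive intervals
#'   (default 0.5).
#' @return object of class `coplot_spec`: list with `intervals` (data.frame:
#'   lower, upper, count, slope, intercept), `indices` (per-interval row
#'   indices into the input), `k`, `overlap`, `target_count`.
#' @export
coplot_intervals <- function(d, f, y, k = 4L, overlap = 0.5) {
  n <- length(d)
  stopifnot(length(f) == n, length(y) == n, k >= 1)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (n < 2 * k) stop("too-few-observations: need at least 2k points")
  ord <- order(d)
  ds <- d[ord]
  m <- n / (k * (1 - overlap) + overlap)
  starts <- round((seq_len(k) - 1) * m * (1 - overlap))
  ends <- pmin(starts + ceiling(m) - 1, n - 1)
  starts <- pmax(starts, 0)
  indices <- vector("list", k)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    sel <- ord[(starts[j] + 1):(ends[j] + 1)]
    indices[[j]] <- sel
    cf <- if (length(unique(f[sel])) > 1)
      stats::coef(stats::lm(y[sel] ~ f[sel])) else c(mean(y[sel]), NA_real_)
    rows[[j]] <- data.frame(interval = j,
                            lower = ds[starts[j] + 1], upper = ds[ends[j] + 1],
                            count = length(sel),
                            intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  structure(list(intervals = do.call(rbind, rows), indices = indices,
                 k = k, overlap = overlap, target_count = m, n = n),
            class = "coplot_spec")
}

#' Serialise a coplot specification to JSON
#' @param spec a `coplot_spec`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coplot_json <- function(spec, path) {
  jsonlite::write_json(list(k = spec$k, overlap = spec$overlap,
                            target_count = spec$target_count, n = spec$n,
                            intervals = spec$intervals,
                            indices = spec$indices),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
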