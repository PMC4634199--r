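#' n-back d-prime: hit rate minus false-alarm rate
#'
#' The working-memory performance score used here is the probability of a
#' correct response minus the probability of a false positive response,
#' i.e. `n_hits/n_targets - n_false_alarms/n_nontargets`. This is a bounded
#' difference of proportions in `[-1, 1]`, not the classical z-transformed
#' signal-detection d'.
#'
#' @param n_hits correct responses to targets (vectorised).
#' @param n_targets number of target trials (> 0).
#' @param n_false_alarms responses to non-targets.
#' @param n_nontargets number of non-target trials (> 0).
#' @return numeric score(s) in `[-1, 1]`.
#' @export
#' @examples
#' dprime(20, 20, 0, 20)   # 1.0
#' dprime(15, 20, 5, 20)   # 0.5
dprime <- function(n_hits, n_targets, n_false_alarms, n_nontargets) {
  if (any(n_targets <= 0) || any(n_nontargets <= 0))
    stop("invalid-counts: trial counts must be positive")
  if (any(n_hits < 0) || any(n_hits > n_targets))
    stop("invalid-counts: hits must lie in [0, n_targets]")
  if (any(n_false_alarms < 0) || any(n_false_alarms > n_nontargets))
    stop("invalid-counts: false alarms must lie in [0, n_nontargets]")
  n_hits / n_targets - n_false_alarms / n_nontargets
}

#' Global cognitive composite from a test battery
#'
#' Standardises each test (mean 0, sd 1) after applying higher-is-better
#' orientation flags, runs a principal component analysis, and returns each
#' subject's score on the first principal component, sign-oriented so that
#' the mean loading is positive (higher composite = better cognition).
#'
#' @param battery numeric matrix or data.frame of test scores (subjects x
#'   tests); the study battery has nine tests but any labelled set works.
#' @param higher_better logical vector per test; tests flagged `FALSE`
#'   (e.g. timing scores) are negated before standardisation. Default all
#'   `TRUE`.
#' @return list with `composite` (per-subject scores), `loadings`,
#'   `var_explained` (per-component proportions), and `n`.
#' @export
cognitive_composite <- function(battery, higher_better = NULL) {
  x <- as.matrix(battery)
  if (!is.numeric(x)) stop("battery must be numeric")
  if (nrow(x) < 10) stop("cognitive_composite: at least 10 subjects required")
  if (anyNA(x))
    stop("missing-data: battery contains NA; handle missingness explicitly")
  if (is.null(higher_better)) higher_better <- rep(TRUE, ncol(x))
  stopifnot(length(higher_better) == ncol(x))
  x[, !higher_better] <- -x[, !higher_better]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop("degeneracy: constant column(s): ", paste(bad, collapse = ", "))
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  sgn <- if (mean(load1) < 0) -1 else 1
  list(composite = sgn * pc$x[, 1],
       loadings = sgn * load1,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       n = nrow(x))
}

#' Add behavioural outcome columns to a cohort table
#'
#' Computes 1-back and 2-back d-prime from the count columns and the PCA
#' cognitive composite from the nine-test battery, and returns the table
#' with `dprime_1back`, `dprime_2back` and `composite` appended.
#'
#' @param records cohort table with n-back count columns and the nine test
#'   columns named as in [cognitive_test_names()].
#' @return the augmented data.frame.
#' @export
add_behavior_metrics <- function(records) {
  records$dprime_1back <- dprime(records$nb1_hits, records$nb1_targets,
                                 records$nb1_false_alarms,
                                 records$nb1_nontargets)
  records$dprime_2back <- dprime(records$nb2_hits, records$nb2_targets,
                                 records$nb2_false_alarms,
                                 records$nb2_nontargets)
  cc <- cognitive_composite(records[, cognitive_test_names()],
                            cognitive_test_orientation())
  records$composite <- cc$composite
  records
}
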