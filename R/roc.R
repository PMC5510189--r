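# Core ROC statistics: Mann-Whitney AUC, partial AUC at fixed specificity,
# permutation p-values, stratified bootstrap confidence intervals.

#' ROC analysis configuration
#'
#' Bundles the resampling settings used by the permutation and bootstrap
#' inference on AUC and partial AUC.
#'
#' @param specificity_floor Specificity at which the partial AUC window ends;
#'   the pAUC integrates the ROC curve over false-positive rate
#'   `[0, 1 - specificity_floor]`. Default 0.95.
#' @param n_permutations Number of label permutations for p-values (default 10000).
#' @param n_bootstrap Number of stratified bootstrap replicates for confidence
#'   intervals (default 2000).
#' @param seed Integer seed controlling all resampling.
#' @param alternative `"greater"` (default; large AUC is the alternative of
#'   interest once transcripts are orientation-fixed) or `"two_sided"`.
#' @return An object of class `roc_config`.
#' @export
roc_config <- function(specificity_floor = 0.95, n_permutations = 10000,
                       n_bootstrap = 2000, seed = 1L,
                       alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!(specificity_floor > 0 && specificity_floor < 1)) {
    abort("specificity_floor must be in (0, 1)")
  }
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (n_bootstrap < 1) abort("n_bootstrap must be >= 1")
  structure(
    list(specificity_floor = specificity_floor,
         n_permutations = as.integer(n_permutations),
         n_bootstrap = as.integer(n_bootstrap),
         seed = as.integer(seed), alternative = alternative),
    class = "roc_config"
  )
}

#' Empirical AUC (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with tied pairs counted 1/2. Computed from midranks, which is
#' exactly the pairwise count.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param labels Per-sample class labels: 0/1, logical, or the outcome strings
#'   `"nonrecurrent"` / `"metastatic_lethal"` (cases = 1 = metastatic-lethal).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1: perfect separation
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  if (length(scores) != length(y)) abort("scores and labels differ in length")
  n1 <- sum(y)
  n0 <- length(y) - n1
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Empirical ROC polygon vertices, ties collapsed: one vertex after each
# distinct score threshold, plus the origin. Trapezoidal area over these
# vertices equals the Mann-Whitney AUC (diagonal segments at tied scores).
roc_points_impl <- function(scores, y) {
  n1 <- sum(y)
  n0 <- length(y) - n1
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yo <- y[o]
  last <- c(s[-length(s)] != s[-1], TRUE) # last index within each tie group
  tpr <- c(0, cumsum(yo)[last] / n1)
  fpr <- c(0, cumsum(1 - yo)[last] / n0)
  list(fpr = fpr, tpr = tpr)
}

#' Empirical ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `fpr` and `tpr`, from (0,0) to (1,1); tied
#'   scores contribute single diagonal segments.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  pts <- roc_points_impl(scores, y)
  tibble::tibble(fpr = pts$fpr, tpr = pts$tpr)
}

# Area under the ROC polygon over fpr in [0, fmax], linearly interpolated at
# the window boundary. Unnormalized: the maximum attainable value is fmax.
pauc_from_points <- function(fpr, tpr, fmax) {
  f1 <- fpr[-length(fpr)]
  f2 <- fpr[-1]
  t1 <- tpr[-length(tpr)]
  t2 <- tpr[-1]
  keep <- f1 < fmax & f2 > f1
  if (!any(keep)) return(0)
  f1 <- f1[keep]; f2 <- f2[keep]; t1 <- t1[keep]; t2 <- t2[keep]
  f2c <- pmin(f2, fmax)
  t2c <- t1 + (t2 - t1) * (f2c - f1) / (f2 - f1)
  sum((f2c - f1) * (t1 + t2c) / 2)
}

#' Partial AUC at fixed specificity
#'
#' Area under the empirical (tie-corrected) ROC curve restricted to
#' false-positive rates below `1 - specificity_floor`, unnormalized, so the
#' maximum attainable value is `1 - specificity_floor` (0.05 at the default
#' 95% specificity) and the chance value is `(1 - specificity_floor)^2 / 2`.
#'
#' @inheritParams roc_auc
#' @param specificity_floor Lower bound on specificity (default 0.95).
#' @return Partial AUC in `[0, 1 - specificity_floor]`.
#' @export
#' @examples
#' roc_pauc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # perfect: 0.05
roc_pauc <- function(scores, labels, specificity_floor = 0.95) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  if (length(scores) != length(y)) abort("scores and labels differ in length")
  pts <- roc_points_impl(scores, y)
  pauc_from_points(pts$fpr, pts$tpr, 1 - specificity_floor)
}

# Fast pAUC given the score ordering (descending) precomputed: yo is the
# 0/1 label vector in that order, last marks tie-group ends.
pauc_ordered <- function(yo, last, n1, n0, fmax) {
  tpr <- c(0, cumsum(yo)[last] / n1)
  fpr <- c(0, cumsum(1 - yo)[last] / n0)
  pauc_from_points(fpr, tpr, fmax)
}

#' Permutation p-value for AUC or partial AUC
#'
#' Permutes the class labels `n_permutations` times and applies the add-one
#' convention `p = (1 + #{perm >= obs}) / (B + 1)`, so p is never zero. For
#' `alternative = "two_sided"` the statistic is recentred at its chance value
#' (0.5 for AUC, `(1-floor)^2/2` for pAUC) and compared in absolute value.
#'
#' @inheritParams roc_auc
#' @param statistic `"auc"` or `"pauc"`.
#' @param cfg A [roc_config()].
#' @return Permutation p-value in `(0, 1]`.
#' @export
roc_permutation_p <- function(scores, labels, statistic = c("auc", "pauc"),
                              cfg = roc_config()) {
  statistic <- match.arg(statistic)
  y <- as_binary_labels(labels)
  check_two_classes(y)
  if (cfg$n_permutations < 1) abort("n_permutations must be >= 1")
  n <- length(y)
  n1 <- sum(y)
  n0 <- n - n1
  B <- cfg$n_permutations
  fmax <- 1 - cfg$specificity_floor

  if (statistic == "auc") {
    r <- rank(scores)
    const <- n1 * (n1 + 1) / 2
    obs <- (sum(r[y == 1]) - const) / (n1 * n0)
    perm <- withr::with_seed(cfg$seed, vapply(seq_len(B), function(b) {
      (sum(r[sample.int(n, n1)]) - const) / (n1 * n0)
    }, numeric(1)))
    centre <- 0.5
  } else {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    last <- c(s[-n] != s[-1], TRUE)
    obs <- pauc_ordered(y[o], last, n1, n0, fmax)
    perm <- withr::with_seed(cfg$seed, vapply(seq_len(B), function(b) {
      pauc_ordered(sample(y)[o], last, n1, n0, fmax)
    }, numeric(1)))
    centre <- fmax^2 / 2
  }

  if (cfg$alternative == "greater") {
    (1 + sum(perm >= obs)) / (B + 1)
  } else {
    (1 + sum(abs(perm - centre) >= abs(obs - centre))) / (B + 1)
  }
}

#' Stratified bootstrap percentile confidence interval for AUC or pAUC
#'
#' Cases and controls are resampled with replacement separately (so every
#' replicate keeps both classes), the statistic recomputed per replicate, and
#' the percentile 2.5%/97.5% interval returned. Replicates on which the
#' statistic is undefined are redrawn (with a logged count).
#'
#' @inheritParams roc_permutation_p
#' @return A named numeric vector `c(lower, upper)`.
#' @export
roc_bootstrap_ci <- function(scores, labels, statistic = c("auc", "pauc"),
                             cfg = roc_config()) {
  statistic <- match.arg(statistic)
  y <- as_binary_labels(labels)
  check_two_classes(y)
  if (sum(y) < 2 || sum(1 - y) < 2) abort("both classes need >= 2 members")
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  stat_fn <- if (statistic == "auc") {
    function(sc, yy) roc_auc(sc, yy)
  } else {
    function(sc, yy) roc_pauc(sc, yy, cfg$specificity_floor)
  }
  yy <- c(rep(1L, length(idx1)), rep(0L, length(idx0)))
  n_redrawn <- 0L
  boot <- withr::with_seed(cfg$seed, vapply(seq_len(cfg$n_bootstrap), function(b) {
    repeat {
      sc <- c(scores[sample(idx1, replace = TRUE)],
              scores[sample(idx0, replace = TRUE)])
      v <- stat_fn(sc, yy)
      if (is.finite(v)) return(v)
      n_redrawn <<- n_redrawn + 1L
    }
  }, numeric(1)))
  if (n_redrawn > 0) inform(sprintf("redrew %d degenerate bootstrap replicates", n_redrawn))
  if (cfg$n_bootstrap == 1) {
    inform("n_bootstrap = 1: degenerate interval with equal bounds")
    return(c(lower = boot, upper = boot))
  }
  q <- quantile(boot, c(0.025, 0.975), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Full ROC summary for one score vector
#'
#' Convenience wrapper computing AUC, pAUC, permutation p-values for both,
#' and stratified bootstrap confidence intervals, as one tibble row.
#'
#' @inheritParams roc_permutation_p
#' @return A one-row tibble with columns `auc`, `pauc`, `p_auc`, `p_pauc`,
#'   `ci_auc_lower`, `ci_auc_upper`, `ci_pauc_lower`, `ci_pauc_upper`.
#' @export
roc_summary <- function(scores, labels, cfg = roc_config()) {
  ci_a <- roc_bootstrap_ci(scores, labels, "auc", cfg)
  ci_p <- roc_bootstrap_ci(scores, labels, "pauc", cfg)
  tibble::tibble(
    auc = roc_auc(scores, labels),
    pauc = roc_pauc(scores, labels, cfg$specificity_floor),
    p_auc = roc_permutation_p(scores, labels, "auc", cfg),
    p_pauc = roc_permutation_p(scores, labels, "pauc", cfg),
    ci_auc_lower = ci_a[["lower"]], ci_auc_upper = ci_a[["upper"]],
    ci_pauc_lower = ci_p[["lower"]], ci_pauc_upper = ci_p[["upper"]]
  )
}
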