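# Mann-Whitney AUC, partial AUC, permutation and bootstrap inference.

brute_force_auc <- function(scores, y) {
  # independent oracle: enumerate all case-control pairs
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cases) * length(controls))
}

test_that("AUC matches pair counting on worked examples", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 5, 4), c(0, 0, 1, 1, 0)), 4 / 6)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals the brute-force pair-count oracle on small inputs with ties", {
  set.seed(42)
  for (n in 3:12) {
    for (rep in 1:20) {
      y <- integer(n)
      while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
      scores <- sample(1:4, n, replace = TRUE) # small alphabet forces ties
      expect_equal(roc_auc(scores, y), brute_force_auc(scores, y))
    }
  }
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    y <- integer(n)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.4)
    s <- sample(1:6, n, replace = TRUE)
    expect_identical(roc_auc(s, y) + roc_auc(-s, y), 1)
  }
})

test_that("pAUC follows the tie-corrected step/diagonal convention", {
  # perfect classifier: sensitivity 1 throughout the FPR window
  expect_equal(roc_pauc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.05)
  # all tied: chance diagonal, integral of t over [0, 0.05]
  expect_equal(roc_pauc(rep(1, 10), rep(0:1, 5)), 0.05^2 / 2)
  # reversed perfect classifier: zero sensitivity at low FPR
  expect_equal(roc_pauc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
})

test_that("pAUC never exceeds min(AUC, window width) and the full window equals AUC", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(6:60, 1)
    y <- integer(n)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.3)
    s <- if (rep %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    a <- roc_auc(s, y)
    p <- roc_pauc(s, y, 0.95)
    expect_lte(p, min(a, 0.05) + 1e-12)
    expect_gte(p, 0)
    # degenerate window covering all FPR recovers the full AUC
    expect_equal(roc_pauc(s, y, specificity_floor = 1e-9), a, tolerance = 1e-6)
  }
})

test_that("AUC and pAUC agree with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (rep in 1:10) {
    n <- 40
    y <- integer(n)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.4)
    s <- rnorm(n)
    r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    expect_equal(roc_auc(s, y), as.numeric(pROC::auc(r)), tolerance = 1e-10)
    pa <- pROC::auc(r, partial.auc = c(1, 0.95), partial.auc.focus = "specificity",
                    partial.auc.correct = FALSE)
    expect_equal(roc_pauc(s, y, 0.95), as.numeric(pa), tolerance = 1e-10)
  }
})

test_that("permutation p-values follow the add-one convention and never reach 0", {
  cfg <- roc_config(n_permutations = 1000, seed = 4)
  # perfect separation: observed exceeds every permuted value
  p <- roc_permutation_p(1:20, rep(0:1, each = 10), "auc", cfg)
  expect_equal(p, 1 / 1001)
  # constant scores: every permutation ties the observed statistic
  expect_equal(roc_permutation_p(rep(3, 12), rep(0:1, 6), "auc", cfg), 1)
  expect_equal(roc_permutation_p(rep(3, 12), rep(0:1, 6), "pauc", cfg), 1)
  # seeded determinism
  set.seed(8)
  s <- rnorm(30)
  y <- rep(0:1, 15)
  expect_identical(roc_permutation_p(s, y, "pauc", cfg),
                   roc_permutation_p(s, y, "pauc", cfg))
  expect_gt(roc_permutation_p(s, y, "auc", cfg), 0)
})

test_that("stratified bootstrap CI behaves at the boundaries", {
  cfg <- roc_config(n_bootstrap = 200, seed = 9)
  # perfectly separated large groups: upper bound 1
  s <- c(rnorm(40, 0), rnorm(40, 20))
  y <- rep(0:1, each = 40)
  ci <- roc_bootstrap_ci(s, y, "auc", cfg)
  expect_equal(ci[["upper"]], 1)
  expect_gt(ci[["lower"]], 0.99)
  # single replicate: degenerate equal bounds, messaged
  cfg1 <- roc_config(n_bootstrap = 1, seed = 9)
  expect_message(ci1 <- roc_bootstrap_ci(s, y, "auc", cfg1), "degenerate")
  expect_identical(ci1[["lower"]], ci1[["upper"]])
  expect_error(roc_bootstrap_ci(c(1, 2, 3), c(0, 1, 1), "auc", cfg), ">= 2 members")
})

test_that("two-sample t-test matches the pooled closed form and is antisymmetric", {
  tt <- welch_t(c(1, 2, 3), c(4, 5, 6), equal_variance = TRUE)
  # pooled variance 1, se = sqrt(2/3): t = -3.674, p = 0.0214
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(tt$statistic, 3), -3.674)
  expect_equal(tt$p_value, 0.0214, tolerance = 0.005)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-3 / sqrt(2 / 3), 4))
  # identical groups
  same <- welch_t(c(1, 2, 5), c(1, 2, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # swap groups: statistic negates, p unchanged
  set.seed(12)
  a <- rnorm(9)
  b <- rnorm(14, 0.5)
  f <- welch_t(a, b)
  r <- welch_t(b, a)
  expect_equal(f$statistic, -r$statistic)
  expect_equal(f$p_value, r$p_value)
  # degenerate zero-variance equal groups
  z <- welch_t(c(2, 2), c(2, 2))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
})

test_that("fold change reproduces published two-decimal values", {
  pub <- published_panel_stats()
  fc <- fold_change(pub$mean_metlethal, pub$mean_nonrecurrent)
  expect_equal(round(fc, 2), pub$fold_change, tolerance = 0.011)
  expect_equal(fold_change(10, 10), 1)
})

test_that("BH q-values match the step-up oracle, support m > n, and are order-invariant", {
  bh_oracle <- function(p, m) {
    # explicit step-up: q_(i) = min_{j >= i} p_(j) * m / j
    o <- order(p)
    k <- length(p)
    q_sorted <- numeric(k)
    for (i in seq_len(k)) {
      q_sorted[i] <- min(1, min(p[o][i:k] * m / (i:k)))
    }
    q <- numeric(k)
    q[o] <- q_sorted
    q
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))^2
    m <- length(p) + sample(0:10, 1)
    q <- suppressMessages(bh_fdr(p, m))
    expect_equal(q, bh_oracle(p, m))
    # order invariance: permute, compute, unpermute
    perm <- sample(length(p))
    expect_equal(suppressMessages(bh_fdr(p[perm], m))[order(perm)], q)
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "m must be")
})

test_that("roc_summary bundles consistent point estimates and intervals", {
  set.seed(30)
  s <- c(rnorm(46), rnorm(32, 1))
  y <- c(rep(0, 46), rep(1, 32))
  cfg <- roc_config(n_permutations = 200, n_bootstrap = 200, seed = 2)
  out <- roc_summary(s, y, cfg)
  expect_equal(out$auc, roc_auc(s, y))
  expect_gte(out$auc, out$ci_auc_lower - 0.1)
  expect_lte(out$pauc, 0.05)
  expect_gt(out$p_auc, 0)
})
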