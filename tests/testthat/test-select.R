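# Logistic fitting, forward selection and bootstrap stability selection.

test_that("intercept-only fit matches the closed form", {
  fit <- fit_logistic(matrix(numeric(0), nrow = 4, ncol = 0), c(0, 0, 1, 1))
  expect_equal(unname(fit$fitted), rep(0.5, 4))
  expect_equal(fit$deviance, 2 * 4 * log(2))
  expect_true(fit$converged)
})

test_that("IRLS agrees with glm on coefficients, errors and deviance", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 150
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 0.9 * x1 - 0.6 * x2))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(cbind(x1 = x1, x2 = x2), y)
    g <- stats::glm(y ~ x1 + x2, family = binomial)
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(f$std_errors),
                 unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
    expect_equal(f$deviance, deviance(g), tolerance = 1e-8)
    td <- tidy(f)
    expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
    expect_equal(glance(f)$deviance, f$deviance)
  }
})

test_that("an exact covariate copy leaves the deviance unchanged with LR statistic 0", {
  set.seed(2)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  f1 <- fit_logistic(cbind(x = x), y)
  f2 <- suppressWarnings(fit_logistic(cbind(x = x, x_copy = x), y))
  expect_equal(f2$deviance, f1$deviance, tolerance = 1e-9)
  expect_true(any(f2$aliased))
  lrt <- lr_test(f1, f2, df = 1)
  expect_equal(lrt$lr_stat, 0, tolerance = 1e-9)
  expect_equal(lrt$p_value, 1)
})

test_that("perfect separation is flagged as non-converged", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(cbind(x = x), y)
  expect_true(fit$separated)
  expect_false(fit$converged)
})

test_that("the slope of a seeded logistic simulation is recovered within 3 SE", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      n <- 300
      x <- rnorm(n)
      y <- rbinom(n, 1, plogis(-1 + x))
      f <- fit_logistic(cbind(x = x), y)
      abs(f$coefficients[["x"]] - 1) < 3 * f$std_errors[["x"]]
    })
  }, logical(1))
  expect_gte(sum(hits), 48)
})

test_that("forward selection picks a strongly planted transcript first under all criteria", {
  coh <- make_planted_cohort(n0 = 200, n1 = 27, n_null = 50, delta = 1.2, seed = 6)
  cands <- coh$expr$probe_id
  cfg <- selection_config(n_stability = 10, min_count = 1, seed = 1)
  for (cr in c("auc", "pauc", "wald")) {
    panel <- forward_select(coh$expr, coh$pheno, cands, cr, cfg)
    expect_equal(panel$transcript_id[1], coh$planted_id)
  }
})

test_that("forward selection stopping rules fire and runs are deterministic", {
  coh <- make_planted_cohort(n0 = 60, n1 = 20, n_null = 20, delta = 0, seed = 7)
  cands <- coh$expr$probe_id
  # an unreachable AUC gain stops at step one with an empty panel
  cfg_hard <- selection_config(min_auc_gain = 0.49, n_stability = 10,
                               min_count = 1, seed = 1)
  empty <- forward_select(coh$expr, coh$pheno, cands, "auc", cfg_hard)
  expect_equal(nrow(empty), 0)
  # deterministic: identical reruns
  cfg <- selection_config(n_stability = 10, min_count = 1, seed = 1)
  a <- forward_select(coh$expr, coh$pheno, cands, "pauc", cfg)
  b <- forward_select(coh$expr, coh$pheno, cands, "pauc", cfg)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  # model AUC is nondecreasing across accepted steps under the AUC criterion
  full <- forward_select(coh$expr, coh$pheno, cands, "auc", cfg)
  if (nrow(full) > 1) expect_true(all(diff(full$metric) >= 0))
  expect_true(all(full$gain >= cfg$min_auc_gain, na.rm = TRUE))
})

test_that("a transcript duplicating the Gleason coding is never selected by Wald", {
  coh <- make_planted_cohort(n0 = 60, n1 = 20, n_null = 5, delta = 0, seed = 8)
  gl_num <- as.numeric(gleason_design(coh$pheno$gleason))
  m <- paucpanel:::expr_matrix(coh$expr)
  m[1, ] <- gl_num # exact linear copy of the base covariate
  expr <- paucpanel:::expr_replace_values(coh$expr, m)
  cfg <- selection_config(n_stability = 10, min_count = 1, seed = 1)
  panel <- forward_select(expr, coh$pheno, expr$probe_id[1], "wald", cfg)
  expect_equal(nrow(panel), 0)
})

test_that("the compiled and reference selection engines agree", {
  coh <- make_planted_cohort(n0 = 80, n1 = 25, n_null = 30, delta = 1.0, seed = 9)
  cfg <- selection_config(n_stability = 10, min_count = 1, seed = 2)
  for (cr in c("auc", "pauc", "wald")) {
    a <- forward_select(coh$expr, coh$pheno, coh$expr$probe_id, cr, cfg, engine = "cpp")
    b <- forward_select(coh$expr, coh$pheno, coh$expr$probe_id, cr, cfg, engine = "r")
    # identical panels up to swaps of numerically tied steps
    expect_setequal(a$transcript_id, b$transcript_id)
    expect_identical(a$transcript_id[1], b$transcript_id[1])
    if (nrow(a) > 0 && cr != "wald") {
      expect_equal(sort(a$metric), sort(b$metric), tolerance = 1e-8)
    }
  }
})

test_that("stability selection with one full-sample replicate reproduces forward selection", {
  coh <- make_planted_cohort(n0 = 60, n1 = 20, n_null = 15, delta = 1.1, seed = 10)
  cfg <- selection_config(n_stability = 1, min_count = 0, seed = 3)
  stab <- stability_select(coh$expr, coh$pheno, coh$expr$probe_id, cfg,
                           bootstrap = FALSE)
  for (cr in c("auc", "pauc", "wald")) {
    fwd <- forward_select(coh$expr, coh$pheno, coh$expr$probe_id, cr, cfg)
    counts <- stab[[paste0("count_", cr)]]
    expect_setequal(stab$transcript_id[counts == 1], fwd$transcript_id)
  }
})

test_that("a planted transcript is robust across bootstrap panels; threshold boundary works", {
  coh <- make_planted_cohort(n0 = 278, n1 = 27, n_null = 50, delta = 1.2, seed = 11)
  cfg <- selection_config(n_stability = 50, min_count = 45, seed = 4)
  stab <- stability_select(coh$expr, coh$pheno, coh$expr$probe_id, cfg)
  row <- stab[stab$transcript_id == coh$planted_id, ]
  expect_gt(row$count_auc, 45)
  expect_gt(row$count_pauc, 45)
  expect_gt(row$count_wald, 45)
  expect_true(row$robust)
  # boundary: with min_count = n_stability - 1, robust requires selection in
  # every single panel
  cfg_b <- selection_config(n_stability = 50, min_count = 49, seed = 4)
  stab_b <- stability_select(coh$expr, coh$pheno, coh$expr$probe_id, cfg_b)
  expect_identical(stab_b$robust, stab_b$max_count == 50L)
  # counts never exceed n_stability
  expect_true(all(stab$max_count <= 50))
  expect_error(selection_config(n_stability = 10, min_count = 10), "min_count")
})
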