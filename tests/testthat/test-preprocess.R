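# Quantile normalization, log2 transform, probe filtering, batch adjustment,
# replicate QC.

test_that("quantile normalization matches the closed form and conserves column means", {
  expr <- make_expr(cbind(c(1, 2), c(3, 4)), is_log2 = FALSE)
  out <- quantile_normalize(expr)
  m <- paucpanel:::expr_matrix(out)
  expect_equal(unname(m[, 1]), c(2, 3))
  expect_equal(unname(m[, 2]), c(2, 3))
  set.seed(2)
  expr2 <- make_expr(matrix(rexp(200 * 5, 1 / 100), 200, 5), is_log2 = FALSE)
  m2 <- paucpanel:::expr_matrix(quantile_normalize(expr2))
  expect_equal(diff(range(colMeans(m2))), 0, tolerance = 1e-9)
})

test_that("quantile normalization equals a rank-then-substitute oracle and limma", {
  qn_oracle <- function(m) {
    # explicitly sort, average order statistics, map back by rank
    ref <- rowMeans(apply(m, 2, sort))
    out <- m
    for (j in seq_len(ncol(m))) {
      rk <- rank(m[, j], ties.method = "average")
      for (i in seq_len(nrow(m))) {
        r <- rk[i]
        lo <- floor(r); hi <- ceiling(r)
        out[i, j] <- (ref[lo] + ref[hi]) / 2
      }
    }
    out
  }
  set.seed(9)
  m <- matrix(sample(1:6, 12, replace = TRUE) + runif(12), 4, 3) # some ties
  m[2, ] <- m[1, ] # force cross-row ties within columns
  got <- paucpanel:::expr_matrix(quantile_normalize(make_expr(m, is_log2 = FALSE)))
  expect_equal(unname(got), unname(qn_oracle(m)))
  skip_if_not_installed("limma")
  expect_equal(unname(got), unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("quantile normalization is idempotent and warns on a single sample", {
  set.seed(4)
  expr <- make_expr(matrix(runif(300, 10, 1000), 100, 3), is_log2 = FALSE)
  once <- quantile_normalize(expr)
  twice <- quantile_normalize(once)
  expect_equal(paucpanel:::expr_matrix(twice), paucpanel:::expr_matrix(once),
               tolerance = 1e-9)
  single <- make_expr(matrix(1:5, 5, 1), is_log2 = FALSE)
  expect_warning(out <- quantile_normalize(single), "single-sample")
  expect_equal(out, single)
})

test_that("log2 transform handles offsets, flags scale, and rejects bad input", {
  expr <- make_expr(cbind(c(8, 0.5), c(1, 0)), is_log2 = FALSE)
  expect_error(log2_transform(expr), "nonpositive value.*TX_002.*S02")
  out <- log2_transform(expr, offset = 1)
  m <- paucpanel:::expr_matrix(out)
  expect_equal(m["TX_002", "S02"], 0)
  expect_true(expression_is_log2(out))
  expect_error(log2_transform(out), "already log2")
  # value 8, offset 0 -> 3
  expect_equal(paucpanel:::expr_matrix(
    log2_transform(make_expr(matrix(8), is_log2 = FALSE)))[1, 1], 3)
})

test_that("probe filtering preserves order, ignores unknowns, is idempotent", {
  set.seed(5)
  expr <- make_expr(matrix(rnorm(500 * 4), 500, 4))
  expect_equal(suppressMessages(filter_probes(expr, expr$probe_id)), expr)
  keep <- c(expr$probe_id[seq(2, 440, by = 2)], "NOT_A_PROBE")
  expect_message(out <- filter_probes(expr, keep), "ignoring 1")
  expect_equal(nrow(out), 220)
  expect_equal(out$probe_id, expr$probe_id[seq(2, 440, by = 2)]) # order kept
  expect_equal(suppressMessages(filter_probes(out, keep)), out)
  expect_error(suppressMessages(filter_probes(expr, c("A", "B"))), "no probes")
  expect_error(filter_probes(expr, character(0)), "nonempty")
})

test_that("batch adjustment removes a pure location effect exactly", {
  set.seed(6)
  g <- 40; n <- 20
  base <- make_expr(matrix(rnorm(g * n, 9, 1), g, n))
  batches <- rep(c("A", "B"), each = n / 2)
  adj_base <- batch_adjust(base, batches)
  pert <- base
  mp <- paucpanel:::expr_matrix(base)
  mp[, batches == "B"] <- mp[, batches == "B"] + 0.5
  pert <- paucpanel:::expr_replace_values(pert, mp)
  adj_pert <- batch_adjust(pert, batches)
  ma <- paucpanel:::expr_matrix(adj_pert)
  mb <- paucpanel:::expr_matrix(adj_base)
  # batch location difference is gone per probe
  d <- rowMeans(ma[, batches == "B"]) - rowMeans(ma[, batches == "A"])
  expect_lt(max(abs(d)), 1e-6)
  # adjusted(perturbed) differs from adjusted(unperturbed) only by the
  # constant global shift the perturbation added to each probe grand mean
  expect_equal(unname(ma - mb), matrix(0.25, g, n), tolerance = 1e-9)
  # probe grand means of the input are preserved
  expect_equal(rowMeans(ma), rowMeans(paucpanel:::expr_matrix(pert)),
               tolerance = 1e-9)
})

test_that("batch adjustment is the identity for literally identical batches", {
  set.seed(7)
  half <- matrix(rnorm(30 * 6, 8, 1.2), 30, 6)
  expr <- make_expr(cbind(half, half))
  out <- batch_adjust(expr, rep(c("A", "B"), each = 6))
  expect_equal(paucpanel:::expr_matrix(out), paucpanel:::expr_matrix(expr),
               tolerance = 1e-9)
})

test_that("batch adjustment suppresses planted batch variance below the null F threshold", {
  set.seed(8)
  g <- 300; n <- 48; nb <- 4
  batches <- rep(paste0("b", 1:nb), each = n / nb)
  offsets <- matrix(rnorm(g * nb, 0, 0.4), g, nb) # per-probe batch effects
  m <- matrix(rnorm(g * n, 9, 0.8), g, n) + offsets[, match(batches, unique(batches))]
  adj <- paucpanel:::expr_matrix(batch_adjust(make_expr(m), batches))
  fstat <- apply(adj, 1, function(row) {
    summary(stats::aov(row ~ factor(batches)))[[1]]$`F value`[1]
  })
  crit <- stats::qf(0.95, nb - 1, n - nb)
  expect_gte(mean(fstat < crit), 0.90)
  # and the raw data would mostly fail the same threshold
  fraw <- apply(m, 1, function(row) {
    summary(stats::aov(row ~ factor(batches)))[[1]]$`F value`[1]
  })
  expect_gt(mean(fraw >= crit), 0.5)
})

test_that("batch adjustment validates its inputs", {
  expr <- make_expr(matrix(rnorm(40), 10, 4))
  expect_error(batch_adjust(expr, c("A", "A", "A", "B")), "batch 'B'")
  expect_error(batch_adjust(expr, rep("A", 4)), ">= 2 batches")
  raw <- make_expr(matrix(runif(40), 10, 4), is_log2 = FALSE)
  expect_error(batch_adjust(raw, rep(c("A", "B"), 2)), "log2")
  # shrinkage keeps probe grand means intact
  set.seed(10)
  e2 <- make_expr(matrix(rnorm(200, 9), 20, 10))
  out <- batch_adjust(e2, rep(c("A", "B"), each = 5), shrink = TRUE)
  expect_equal(rowMeans(paucpanel:::expr_matrix(out)),
               rowMeans(paucpanel:::expr_matrix(e2)), tolerance = 1e-9)
})

test_that("replicate QC reports per-pair correlations and flags failures", {
  set.seed(11)
  g <- 2000
  x <- rnorm(g, 10, 2)
  m <- cbind(x, x, x + rnorm(g, 0, 0.1), rnorm(g, 10, 2))
  expr <- make_expr(m, sample_ids = c("S01", "S02", "S03", "S04"))
  pheno <- make_pheno(2, 2, sample_ids = c("S01", "S02", "S03", "S04"))
  pheno$replicate_of <- c(NA, "S01", "S01", NA)
  qc <- replicate_qc(expr, pheno)
  expect_equal(nrow(qc), 2)
  expect_equal(qc$correlation[1], 1.0) # duplicated column
  expect_gt(qc$correlation[2], 0.98)   # noisy duplicate, matches assay QC range
  expect_false(any(qc$flagged))
  # a noise pair is flagged
  pheno$replicate_of <- c(NA, NA, NA, "S01")
  expect_warning(qc2 <- replicate_qc(expr, pheno), "below correlation")
  expect_true(qc2$flagged)
  # absent sample is an error
  pheno$replicate_of <- c(NA, "GHOST", NA, NA)
  expect_error(replicate_qc(expr, pheno), "GHOST")
  # no pairs: empty, messaged
  pheno$replicate_of <- NA_character_
  expect_message(empty <- replicate_qc(expr, pheno), "no replicate")
  expect_equal(nrow(empty), 0)
})

test_that("expression and phenotype readers validate structure with coordinates", {
  dir <- withr::local_tempdir()
  expr <- make_expr(matrix(1:12 + 0.25, 3, 4), is_log2 = FALSE)
  p_expr <- file.path(dir, "e.tsv")
  write_expression(expr, p_expr)
  back <- read_expression(p_expr)
  expect_equal(dim(paucpanel:::expr_matrix(back)), c(3L, 4L))
  expect_equal(paucpanel:::expr_matrix(back), paucpanel:::expr_matrix(expr))
  # repeated sample column
  lines <- readLines(p_expr)
  lines[1] <- sub("S02", "S01", lines[1])
  writeLines(lines, p_expr)
  expect_error(read_expression(p_expr), "repeated column.*S01")
  # non-numeric intensity
  write_expression(expr, p_expr)
  lines <- readLines(p_expr)
  lines[2] <- sub("1.25", "abc", lines[2], fixed = TRUE)
  writeLines(lines, p_expr)
  suppressWarnings(expect_error(read_expression(p_expr), "non-numeric"))
  # phenotype: missing stage level is legal, unknown label is not
  ph <- make_pheno(3, 2)
  ph$stage[1] <- "missing"
  p_ph <- file.path(dir, "p.tsv")
  write_phenotype(ph, p_ph)
  expect_silent(read_phenotype(p_ph))
  ph$gleason[2] <- "gleason9"
  write_phenotype(ph, p_ph)
  expect_error(read_phenotype(p_ph), "unknown gleason label 'gleason9'")
  ph <- make_pheno(3, 2)
  ph$sample_id[2] <- ph$sample_id[1]
  write_phenotype(ph, p_ph)
  expect_error(read_phenotype(p_ph), "duplicate sample_id")
})
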