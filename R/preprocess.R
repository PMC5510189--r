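# Preprocessing: quantile normalization, log2 transform, probe filtering,
# location-scale batch adjustment, replicate quality control.

#' Quantile-normalize an expression table
#'
#' Forces every sample column onto the identical empirical distribution: the
#' reference is the across-sample mean of order statistics, and each column's
#' values are replaced by the reference values at their ranks. Ties receive
#' the mean of the reference at the tied ranks (midranks are interpolated
#' linearly), which makes the operation deterministic and idempotent.
#'
#' Applied before the log2 transform (raw-intensity input).
#'
#' @param expr Expression tibble (raw scale).
#' @return The normalized expression tibble.
#' @export
quantile_normalize <- function(expr) {
  validate_expression(expr)
  if (expression_is_log2(expr)) {
    abort("quantile_normalize expects raw intensities (normalize before log2)")
  }
  m <- expr_matrix(expr)
  if (ncol(m) == 1) {
    warn("single-sample matrix: quantile normalization is a no-op")
    return(expr)
  }
  g <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    if (g == 1) return(ref)
    stats::approx(seq_len(g), ref, xout = rk)$y
  })
  dimnames(out) <- dimnames(m)
  expr_replace_values(expr, out)
}

#' Log2-transform an expression table
#'
#' Elementwise `log2(value + offset)`; flags the result as log2-scale.
#' Re-transforming an already log2 table, or any nonpositive shifted value,
#' is an error (naming the offending entry).
#'
#' @param expr Expression tibble (raw scale).
#' @param offset Nonnegative value added before the log (default 0).
#' @return The transformed expression tibble.
#' @export
log2_transform <- function(expr, offset = 0) {
  validate_expression(expr)
  if (expression_is_log2(expr)) abort("expression table is already log2-transformed")
  m <- expr_matrix(expr)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("nonpositive value after offset at probe '%s', sample '%s'",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  set_log2_flag(expr_replace_values(expr, log2(m + offset)), TRUE)
}

#' Restrict an expression table to a probe keep-list
#'
#' Keeps probes present in `keep_list`, preserving the table's probe order.
#' Keep-list identifiers absent from the table are ignored with a message;
#' a keep-list disjoint from the table is an error.
#'
#' @param expr Expression tibble.
#' @param keep_list Character vector of probe identifiers (or a path handled
#'   by [read_keep_list()]).
#' @return The filtered expression tibble.
#' @export
filter_probes <- function(expr, keep_list) {
  validate_expression(expr)
  if (length(keep_list) == 0) abort("keep_list must be nonempty")
  unknown <- setdiff(keep_list, expr$probe_id)
  if (length(unknown) == length(unique(keep_list))) {
    abort("keep_list shares no probes with the expression table")
  }
  if (length(unknown) > 0) {
    inform(sprintf("ignoring %d keep-list id(s) absent from the table", length(unknown)))
  }
  flag <- expression_is_log2(expr)
  out <- expr[expr$probe_id %in% keep_list, , drop = FALSE]
  inform(sprintf("probe filter: %d of %d probes retained", nrow(out), nrow(expr)))
  set_log2_flag(out, flag)
}

#' Read a probe keep-list (one identifier per line)
#' @param path Plain-text file path.
#' @return Character vector of probe identifiers.
#' @export
read_keep_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("keep list not found: %s", path))
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Location-scale batch adjustment
#'
#' Removes per-probe batch location and scale effects from log2 data: within
#' each batch, values are centred at the batch mean and rescaled to the
#' pooled within-batch standard deviation, then the probe's grand mean is
#' added back (and exactly restored, so the probe grand mean is preserved).
#' With `shrink = TRUE`, each probe's batch means and SDs are shrunk toward
#' their across-probe batch averages with weight `n_batch / (n_batch + 1)`,
#' damping noisy per-probe batch estimates.
#'
#' @param expr Expression tibble (log2 scale).
#' @param batches Per-sample batch labels in expression column order, or a
#'   phenotype tibble with `sample_id` and `batch` columns.
#' @param shrink Shrink batch means/SDs toward their across-probe averages.
#' @return The adjusted expression tibble.
#' @export
batch_adjust <- function(expr, batches, shrink = FALSE) {
  validate_expression(expr)
  if (!expression_is_log2(expr)) abort("batch_adjust expects log2-scale data")
  m <- expr_matrix(expr)
  if (is.data.frame(batches)) {
    batches <- align_phenotype(expr, batches)$batch
  }
  if (length(batches) != ncol(m)) abort("one batch label per sample is required")
  batches <- as.character(batches)
  tab <- table(batches)
  if (length(tab) < 2) abort("batch_adjust needs >= 2 batches")
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    abort(sprintf("batch '%s' has fewer than 2 samples", small[1]))
  }

  gm <- rowMeans(m)
  n <- ncol(m)
  nb <- length(tab)
  batch_names <- names(tab)
  # per-probe, per-batch means and SDs
  bm <- sapply(batch_names, function(b) rowMeans(m[, batches == b, drop = FALSE]))
  bs <- sapply(batch_names, function(b) apply(m[, batches == b, drop = FALSE], 1, sd))
  if (shrink) {
    for (j in seq_len(nb)) {
      w <- tab[[j]] / (tab[[j]] + 1)
      bm[, j] <- w * bm[, j] + (1 - w) * mean(bm[, j])
      bs[, j] <- w * bs[, j] + (1 - w) * mean(bs[, j])
    }
  }
  dfree <- n - nb
  s_pool <- sqrt(rowSums(sweep(bs^2, 2, as.numeric(tab) - 1, `*`)) / max(dfree, 1))

  out <- m
  for (j in seq_len(nb)) {
    sel <- batches == batch_names[j]
    scale_j <- ifelse(bs[, j] > 0, s_pool / bs[, j], 1)
    out[, sel] <- (m[, sel, drop = FALSE] - bm[, j]) * scale_j + gm
  }
  # restore each probe's grand mean exactly
  out <- out - rowMeans(out) + gm
  expr_replace_values(expr, out)
}

#' Replicate-pair quality control
#'
#' Pearson correlation across probes for every replicate pair declared in the
#' phenotype `replicate_of` column. Pairs below `threshold` are flagged.
#'
#' @param expr Expression tibble.
#' @param pheno Phenotype tibble with a `replicate_of` column.
#' @param threshold Correlation below which a pair is flagged (default 0.95).
#' @return A tibble with `sample_id`, `replicate_of`, `correlation`, `flagged`.
#' @export
replicate_qc <- function(expr, pheno, threshold = 0.95) {
  validate_expression(expr)
  validate_phenotype(pheno)
  if (!"replicate_of" %in% names(pheno)) {
    inform("no replicate_of column: no replicate pairs to check")
    return(tibble::tibble(sample_id = character(), replicate_of = character(),
                          correlation = numeric(), flagged = logical()))
  }
  pairs <- pheno[!is.na(pheno$replicate_of) & nzchar(pheno$replicate_of),
                 c("sample_id", "replicate_of")]
  if (nrow(pairs) == 0) {
    inform("no replicate pairs declared")
    return(tibble::tibble(sample_id = character(), replicate_of = character(),
                          correlation = numeric(), flagged = logical()))
  }
  m <- expr_matrix(expr)
  absent <- setdiff(unlist(pairs), colnames(m))
  if (length(absent) > 0) {
    abort(sprintf("replicate pair names sample(s) absent from expression: %s",
                  paste(absent, collapse = ", ")))
  }
  out <- purrr::pmap_dfr(pairs, function(sample_id, replicate_of) {
    tibble::tibble(sample_id = sample_id, replicate_of = replicate_of,
                   correlation = stats::cor(m[, sample_id], m[, replicate_of]))
  })
  out$flagged <- out$correlation < threshold
  if (any(out$flagged)) {
    warn(sprintf("%d replicate pair(s) below correlation %.2f",
                 sum(out$flagged), threshold))
  }
  out
}
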