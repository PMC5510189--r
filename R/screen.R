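# Genomewide per-transcript ROC screening and dual-rank candidate reduction.

rank_cutoff <- function(m, fraction) max(1L, floor(m * fraction))

# Descending rank with deterministic ties: higher metric first, probe order
# (i.e., transcript identifier order within the table) breaks ties.
rank_desc <- function(metric) {
  ord <- order(-metric, seq_along(metric))
  rk <- integer(length(metric))
  rk[ord] <- seq_along(metric)
  rk
}

#' Screen every transcript by AUC and partial AUC
#'
#' For each transcript, its expression values are oriented so that AUC >= 0.5
#' (the orientation sign is recorded; an AUC of exactly 0.5 keeps sign +1),
#' then AUC and pAUC at the configured specificity are computed and ranked.
#' A transcript enters the candidate panel when it ranks in the top
#' `top_pauc_fraction` by pAUC or (default `combine_rule = "union"`) the top
#' `top_auc_fraction` by AUC; rank cutoffs are `floor(m * fraction)` with a
#' minimum of 1.
#'
#' @param expr Expression tibble (log2 scale).
#' @param pheno Phenotype tibble; outcome must contain both classes.
#' @param top_pauc_fraction Fraction of transcripts kept by pAUC rank (default 0.04).
#' @param top_auc_fraction Fraction kept by AUC rank (default 0.01).
#' @param combine_rule `"union"` (default) or `"intersection"`.
#' @param specificity_floor Specificity bound for the pAUC (default 0.95).
#' @return A tibble of class `screen_result`: `transcript_id`, `gene`,
#'   `auc`, `pauc`, `rank_auc`, `rank_pauc`, `orientation`, `selected`.
#' @export
screen_transcripts <- function(expr, pheno, top_pauc_fraction = 0.04,
                               top_auc_fraction = 0.01,
                               combine_rule = c("union", "intersection"),
                               specificity_floor = 0.95) {
  combine_rule <- match.arg(combine_rule)
  validate_expression(expr)
  if (nrow(expr) == 0) abort("empty expression matrix")
  pheno <- align_phenotype(expr, pheno)
  y <- as_binary_labels(pheno$outcome)
  check_two_classes(y)
  m <- expr_matrix(expr)
  n1 <- sum(y)
  n0 <- length(y) - n1
  const <- n1 * (n1 + 1) / 2
  fmax <- 1 - specificity_floor

  stats <- vapply(seq_len(nrow(m)), function(i) {
    sc <- m[i, ]
    a <- (sum(rank(sc)[y == 1]) - const) / (n1 * n0)
    orient <- if (a >= 0.5) 1 else -1
    sc2 <- sc * orient
    c(auc = max(a, 1 - a),
      pauc = roc_pauc(sc2, y, specificity_floor),
      orientation = orient)
  }, numeric(3))

  n_tx <- nrow(m)
  res <- tibble::tibble(
    transcript_id = expr$probe_id,
    gene = if ("gene" %in% names(expr)) expr$gene else NA_character_,
    auc = stats["auc", ],
    pauc = stats["pauc", ],
    orientation = as.integer(stats["orientation", ])
  )
  res$rank_auc <- rank_desc(res$auc)
  res$rank_pauc <- rank_desc(res$pauc)
  cut_auc <- rank_cutoff(n_tx, top_auc_fraction)
  cut_pauc <- rank_cutoff(n_tx, top_pauc_fraction)
  in_auc <- res$rank_auc <= cut_auc
  in_pauc <- res$rank_pauc <= cut_pauc
  res$selected <- if (combine_rule == "union") in_auc | in_pauc else in_auc & in_pauc
  if (any(res$auc == 0.5)) {
    inform(sprintf("%d transcript(s) with AUC exactly 0.5 oriented +1 by convention",
                   sum(res$auc == 0.5)))
  }
  structure(res, class = c("screen_result", class(res)),
            cutoffs = c(auc = cut_auc, pauc = cut_pauc),
            fractions = c(auc = top_auc_fraction, pauc = top_pauc_fraction),
            combine_rule = combine_rule,
            specificity_floor = specificity_floor)
}

#' Discovery orientation map of a screen result
#'
#' Sign +1 when raw expression is positively associated with the
#' metastatic-lethal class, -1 otherwise; used downstream to orient
#' validation scores and check direction concordance.
#'
#' @param result A `screen_result`.
#' @return A tibble with `transcript_id` and `orientation`.
#' @export
orientation_map <- function(result) {
  stopifnot(inherits(result, "screen_result") ||
              all(c("transcript_id", "orientation") %in% names(result)))
  tibble::as_tibble(result)[, c("transcript_id", "orientation")]
}
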