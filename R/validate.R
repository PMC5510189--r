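# Independent-cohort evaluation of a robust-marker panel.

#' Validate a transcript panel in an independent cohort
#'
#' For each panel transcript: group mean log2 expressions, their difference
#' (metastatic-lethal minus nonrecurrent), fold change; AUC and pAUC on
#' discovery-oriented scores with permutation p-values and stratified
#' bootstrap confidence intervals; a two-sided t-test; Benjamini-Hochberg
#' q-values across the panel (family size `m_fdr`, default the panel size);
#' and direction concordance (validation difference sign equals the
#' discovery orientation). A transcript is declared validated when any of
#' the AUC, pAUC or t-test p-values is below `alpha` and its q-value is
#' below `fdr_threshold`.
#'
#' @param expr Validation-cohort expression tibble (log2 scale).
#' @param pheno Validation-cohort phenotype tibble.
#' @param panel Tibble with `transcript_id` and discovery `orientation`
#'   (+1/-1), e.g. from [orientation_map()] filtered to robust markers.
#' @param cfg A [roc_config()]; per-transcript resampling seeds are derived
#'   from `cfg$seed` and the transcript identifier.
#' @param alpha Per-test significance threshold (default 0.05, two-tailed
#'   for the t-test).
#' @param fdr_threshold FDR threshold considered noteworthy (default 0.20).
#' @param m_fdr BH family size (default `nrow(panel)`).
#' @return A tibble of class `validation_result`, one row per transcript:
#'   means, difference, fold change, AUC/pAUC with p-values and CIs, t-test
#'   p, q-value, `direction_concordant`, `validated`.
#' @export
validate_panel <- function(expr, pheno, panel, cfg = roc_config(),
                           alpha = 0.05, fdr_threshold = 0.20,
                           m_fdr = nrow(panel)) {
  validate_expression(expr)
  stopifnot(all(c("transcript_id", "orientation") %in% names(panel)))
  if (nrow(panel) == 0) abort("panel must be nonempty")
  absent <- setdiff(panel$transcript_id, expr$probe_id)
  if (length(absent) > 0) {
    abort(sprintf("panel transcript(s) absent from validation matrix: %s",
                  paste(absent, collapse = ", ")))
  }
  pheno <- align_phenotype(expr, pheno)
  y <- as_binary_labels(pheno$outcome)
  check_two_classes(y)
  m <- expr_matrix(expr)
  annot <- tibble::as_tibble(expr)[, intersect(names(expr), EXPR_ANNOT_COLS)]

  rows <- purrr::map2_dfr(panel$transcript_id, panel$orientation, function(id, orient) {
    vals <- m[id, ]
    mean0 <- mean(vals[y == 0])
    mean1 <- mean(vals[y == 1])
    diff <- mean1 - mean0
    scores <- vals * orient
    tcfg <- cfg
    tcfg$seed <- derive_seed(cfg$seed, id)
    tt <- welch_t(vals[y == 1], vals[y == 0])
    ci_a <- roc_bootstrap_ci(scores, y, "auc", tcfg)
    ci_p <- roc_bootstrap_ci(scores, y, "pauc", tcfg)
    tibble::tibble(
      transcript_id = id,
      mean_nonrecurrent = mean0,
      mean_metlethal = mean1,
      difference = diff,
      fold_change = fold_change(mean1, mean0),
      auc = roc_auc(scores, y),
      p_auc = roc_permutation_p(scores, y, "auc", tcfg),
      pauc = roc_pauc(scores, y, cfg$specificity_floor),
      p_pauc = roc_permutation_p(scores, y, "pauc", tcfg),
      ci_auc_lower = ci_a[["lower"]], ci_auc_upper = ci_a[["upper"]],
      ci_pauc_lower = ci_p[["lower"]], ci_pauc_upper = ci_p[["upper"]],
      p_ttest = tt$p_value,
      direction_concordant = (diff * orient) > 0,
      orientation = orient
    )
  })
  rows$q_value <- bh_fdr(rows$p_ttest, m = m_fdr)
  rows$validated <- (rows$p_auc < alpha | rows$p_pauc < alpha |
                       rows$p_ttest < alpha) & rows$q_value < fdr_threshold
  out <- dplyr::left_join(rows,
                          dplyr::rename(annot, transcript_id = "probe_id"),
                          by = "transcript_id")
  keep_first <- intersect(c("transcript_id", "gene", "chromosome"), names(out))
  out <- dplyr::relocate(out, dplyr::all_of(keep_first))
  structure(out, class = c("validation_result", class(out)),
            alpha = alpha, fdr_threshold = fdr_threshold, m_fdr = m_fdr)
}

#' Gleason + transcript combined models with likelihood-ratio tests
#'
#' Fits the Gleason-only logistic model and, for each transcript, the
#' Gleason + transcript model on the validation cohort; reports in-sample
#' AUC and pAUC of the fitted probabilities and the likelihood-ratio test
#' (deviance difference, chi-square with 1 df) of the transcript term.
#' Fits with separation are flagged and their metrics left missing.
#'
#' @param expr Validation-cohort expression tibble (log2 scale).
#' @param pheno Validation-cohort phenotype tibble.
#' @param transcripts Character vector of transcript identifiers.
#' @param gleason_coding Gleason coding for both models (default ordinal).
#' @param specificity_floor pAUC specificity bound (default 0.95).
#' @return A tibble with one row per transcript: `gleason_auc`,
#'   `gleason_pauc`, `combined_auc`, `combined_pauc`, `lr_stat`, `p_lrt`,
#'   `converged`.
#' @export
combined_model <- function(expr, pheno, transcripts,
                           gleason_coding = c("ordinal", "categorical"),
                           specificity_floor = 0.95) {
  gleason_coding <- match.arg(gleason_coding)
  validate_expression(expr)
  absent <- setdiff(transcripts, expr$probe_id)
  if (length(absent) > 0) {
    abort(sprintf("transcript(s) absent from validation matrix: %s",
                  paste(absent, collapse = ", ")))
  }
  pheno <- align_phenotype(expr, pheno)
  y <- as_binary_labels(pheno$outcome)
  check_two_classes(y)
  m <- expr_matrix(expr)
  base <- gleason_design(pheno$gleason, gleason_coding)
  base_fit <- fit_logistic(base, y)
  if (!base_fit$converged) abort("Gleason-only model did not converge")
  g_auc <- roc_auc(base_fit$fitted, y)
  g_pauc <- roc_pauc(base_fit$fitted, y, specificity_floor)

  purrr::map_dfr(transcripts, function(id) {
    fit <- fit_logistic(cbind(base, transcript = m[id, ]), y)
    if (fit$separated) {
      return(tibble::tibble(transcript_id = id, gleason_auc = g_auc,
                            gleason_pauc = g_pauc, combined_auc = NA_real_,
                            combined_pauc = NA_real_, lr_stat = NA_real_,
                            p_lrt = NA_real_, converged = FALSE))
    }
    lrt <- lr_test(base_fit, fit, df = 1)
    tibble::tibble(
      transcript_id = id, gleason_auc = g_auc, gleason_pauc = g_pauc,
      combined_auc = roc_auc(fit$fitted, y),
      combined_pauc = roc_pauc(fit$fitted, y, specificity_floor),
      lr_stat = lrt$lr_stat, p_lrt = lrt$p_value, converged = fit$converged
    )
  })
}
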