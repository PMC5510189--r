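# Report renderers: cohort descriptive table, validation table, and
# Gleason-combined model table, in journal-table style.

descr_labels <- list(
  gleason = c(leq6 = "<= 6", g3p4 = "7(3+4)", g4p3 = "7(4+3)", g8to10 = "8-10"),
  stage = c(local = "Local", regional = "Regional", missing = "Missing"),
  psa_cat = c(lt4 = "< 4.0", c4to9 = "4.0-9.9", c10to19 = "10.0-19.9",
              ge20 = ">= 20", missing = "Missing")
)

#' Cohort descriptive table (characteristics by outcome)
#'
#' Counts and percentages per outcome group for Gleason score, pathological
#' stage and PSA category (chi-square test across non-missing levels), and
#' mean (SD) age with a t-test. Percentages are reported to one decimal;
#' categorical p-values below 0.01 render as `"< 0.01"`.
#'
#' @param pheno Phenotype tibble.
#' @return A tibble: `variable`, `level`, `n_nonrecurrent`,
#'   `pct_nonrecurrent`, `n_metlethal`, `pct_metlethal`, `p_value`.
#' @export
descriptive_table <- function(pheno) {
  validate_phenotype(pheno)
  y <- as_binary_labels(pheno$outcome)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  fmt_p <- function(p) if (is.na(p)) NA_character_ else if (p < 0.01) "< 0.01" else formatC(p, format = "f", digits = 2)

  rows <- list()
  if ("age" %in% names(pheno) && is.numeric(pheno$age)) {
    a0 <- pheno$age[y == 0]
    a1 <- pheno$age[y == 1]
    p_age <- if (length(a0) >= 2 && length(a1) >= 2) welch_t(a0, a1)$p_value else NA_real_
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = "age", level = sprintf("mean (SD) %.1f (%.1f) vs %.1f (%.1f)",
                                        mean(a0), sd(a0), mean(a1), sd(a1)),
      n_nonrecurrent = n0, pct_nonrecurrent = NA_real_,
      n_metlethal = n1, pct_metlethal = NA_real_, p_value = fmt_p(p_age)
    )
  }
  for (var in intersect(c("gleason", "stage", "psa_cat"), names(pheno))) {
    levels_all <- switch(var, gleason = gleason_levels(),
                         stage = stage_levels(), psa_cat = psa_levels())
    c0 <- vapply(levels_all, function(l) sum(pheno[[var]][y == 0] == l, na.rm = TRUE), integer(1))
    c1 <- vapply(levels_all, function(l) sum(pheno[[var]][y == 1] == l, na.rm = TRUE), integer(1))
    informative <- levels_all != "missing" & (c0 + c1) > 0
    p_var <- if (sum(informative) >= 2 && sum(c0[informative]) > 0 && sum(c1[informative]) > 0) {
      suppressWarnings(chisq.test(cbind(c0[informative], c1[informative]))$p.value)
    } else {
      NA_real_
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = var, level = unname(descr_labels[[var]][levels_all]),
      n_nonrecurrent = unname(c0), pct_nonrecurrent = unname(format_pct(c0 / n0)),
      n_metlethal = unname(c1), pct_metlethal = unname(format_pct(c1 / n1)),
      p_value = c(fmt_p(p_var), rep(NA_character_, length(levels_all) - 1))
    )
  }
  dplyr::bind_rows(rows)
}

#' Render a validation result as a publication-style table
#'
#' Means, differences, fold changes and AUCs to two decimals, pAUC to four;
#' p-values in scientific notation below 0.01 and floored at `1e-6`
#' (rendered as an inequality).
#'
#' @param records A `validation_result` from [validate_panel()].
#' @return A character-column tibble mirroring the validated-transcripts
#'   table layout.
#' @export
validation_table <- function(records) {
  if (nrow(records) == 0) abort("records must be nonempty")
  tibble::tibble(
    transcript_id = records$transcript_id,
    gene = if ("gene" %in% names(records)) records$gene else NA_character_,
    chromosome = if ("chromosome" %in% names(records)) records$chromosome else NA_character_,
    mean_nonrecurrent = sprintf("%.2f", records$mean_nonrecurrent),
    mean_metlethal = sprintf("%.2f", records$mean_metlethal),
    difference = sprintf("%.2f", records$difference),
    fold_change = sprintf("%.2f", records$fold_change),
    auc = sprintf("%.2f", records$auc),
    p_auc = format_pvalue(records$p_auc),
    pauc = sprintf("%.4f", records$pauc),
    p_pauc = format_pvalue(records$p_pauc),
    p_ttest = format_pvalue(records$p_ttest),
    q_value = format_pvalue(records$q_value),
    validated = ifelse(records$validated, "yes", "no")
  )
}

#' Render combined-model results as a publication-style table
#'
#' @param combined Output of [combined_model()].
#' @return A character-column tibble: AUC to two decimals, pAUC to four,
#'   LR p-values in scientific notation below 0.01.
#' @export
model_comparison_table <- function(combined) {
  if (nrow(combined) == 0) abort("records must be nonempty")
  tibble::tibble(
    transcript_id = combined$transcript_id,
    combined_auc = sprintf("%.2f", combined$combined_auc),
    combined_pauc = sprintf("%.4f", combined$combined_pauc),
    p_lrt = format_pvalue(combined$p_lrt),
    gleason_auc = sprintf("%.2f", combined$gleason_auc),
    gleason_pauc = sprintf("%.4f", combined$gleason_pauc)
  )
}
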