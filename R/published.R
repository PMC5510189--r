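# Access to the bundled worked-example table.

#' Published 23-transcript prognostic panel summary statistics
#'
#' Validation-cohort summary statistics of a published 23-transcript panel
#' for classifying metastatic-lethal vs. nonrecurrent prostate cancer:
#' group mean log2 expressions, their difference, fold change, AUC, pAUC at
#' 95% specificity, two-sided t-test p-values and BH q-values (computed with
#' family size 48, the size of the robust panel carried into validation).
#' Used in worked examples and convention checks: the printed fold changes
#' and q-values are recomputable from the printed means and t-test p-values
#' with [fold_change()] and [bh_fdr()].
#'
#' @return A 23-row tibble.
#' @export
published_panel_stats <- function() {
  path <- system.file("extdata", "published_panel_stats.tsv",
                      package = "paucpanel", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(), gene = readr::col_character(),
    chromosome = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
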