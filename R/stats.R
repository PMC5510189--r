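# Two-sample t-test, fold change, and Benjamini-Hochberg FDR.

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (the safer choice with the
#' unbalanced group sizes typical of outcome cohorts); set
#' `equal_variance = TRUE` for the pooled-variance form. Two constant,
#' equal groups return statistic 0 and p 1 rather than an error.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @param equal_variance Use the pooled-variance t-test (default `FALSE`).
#' @return A tibble with columns `statistic`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6), equal_variance = TRUE)
welch_t <- function(values_a, values_b, equal_variance = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs >= 2 values")
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(tibble::tibble(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                          df = NA_real_, p_value = 0))
  }
  tt <- t.test(values_a, values_b, var.equal = equal_variance)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Fold change from group mean log2 expressions
#'
#' On log2-scale data the ratio of group geometric means is
#' `2^(mean_case - mean_control)`.
#'
#' @param mean_log2_case,mean_log2_control Group means on the log2 scale.
#' @return Fold change (case / control).
#' @export
#' @examples
#' fold_change(10.39, 11.44) # 0.48: down-regulated in cases
fold_change <- function(mean_log2_case, mean_log2_control) {
  2^(mean_log2_case - mean_log2_control)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. `m` may exceed the number of p-values supplied,
#' for the case where only a subset of a larger family is carried forward
#' (the remaining tests are assumed to have larger p-values); this is
#' messaged when it happens.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Size of the test family; defaults to `length(p_values)`.
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) abort("p_values must be nonempty")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    abort("p_values must lie in [0, 1]")
  }
  if (m < length(p_values)) abort("m must be >= length(p_values)")
  if (m > length(p_values)) {
    inform(sprintf("BH family size m = %d exceeds the %d p-values supplied; the %d tests not carried forward are assumed less significant",
                   m, length(p_values), m - length(p_values)))
  }
  p.adjust(p_values, method = "BH", n = m)
}
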