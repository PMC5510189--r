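# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps a global integer seed and a text label (stage or
#' transcript name) to a new seed, so that pipeline stages never reuse the
#' same random stream. The result is always a positive 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the consumer of the derived seed.
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(42, "screening")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 17) %% 2147483629 + 1)
}

# Coerce labels to 0/1 with 1 = case (metastatic-lethal).
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("nonrecurrent", "metastatic_lethal")
    if (!all(ok)) {
      abort(sprintf("unknown outcome label(s): %s",
                    paste(unique(labels[!ok]), collapse = ", ")))
    }
    return(as.integer(labels == "metastatic_lethal"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1, logical, or outcome strings")
  as.integer(labels)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present", class = "paucpanel_single_class")
  }
  invisible(y)
}

# Gleason categories in display order, with readable labels.
gleason_levels <- function() c("leq6", "g3p4", "g4p3", "g8to10")
stage_levels <- function() c("local", "regional", "missing")
psa_levels <- function() c("lt4", "c4to9", "c10to19", "ge20", "missing")
outcome_levels <- function() c("nonrecurrent", "metastatic_lethal")

#' Numeric Gleason coding used by the base logistic model
#'
#' Codes the four Gleason categories (<=6, 3+4, 4+3, 8-10) as 1..4 (ordinal,
#' the default base-model predictor) or as an indicator matrix (categorical).
#'
#' @param gleason Character vector of Gleason categories.
#' @param coding `"ordinal"` (single 1-4 column) or `"categorical"`
#'   (three indicator columns, `leq6` as reference).
#' @return A numeric matrix with one row per sample.
#' @export
gleason_design <- function(gleason, coding = c("ordinal", "categorical")) {
  coding <- match.arg(coding)
  lv <- gleason_levels()
  idx <- match(gleason, lv)
  if (anyNA(idx)) {
    abort(sprintf("unknown gleason category: %s",
                  paste(unique(gleason[is.na(idx)]), collapse = ", ")))
  }
  if (coding == "ordinal") {
    matrix(idx, ncol = 1, dimnames = list(NULL, "gleason"))
  } else {
    out <- sapply(lv[-1], function(l) as.numeric(gleason == l))
    colnames(out) <- paste0("gleason_", lv[-1])
    out
  }
}

format_pct <- function(x) round(100 * x, 1)

#' Format a p-value for report tables
#'
#' P-values below `sci_below` are rendered in scientific notation with three
#' significant digits; very small values are floored at `floor` and shown as
#' an inequality, mirroring common journal-table style.
#'
#' @param p Numeric vector of p-values.
#' @param sci_below Threshold below which scientific notation is used.
#' @param floor Smallest displayable value; smaller p render as `"< floor"`.
#' @return Character vector.
#' @export
format_pvalue <- function(p, sci_below = 0.01, floor = 1e-6) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < floor) return(sprintf("< %s", format(floor, scientific = TRUE)))
    if (pi < sci_below) return(formatC(pi, format = "e", digits = 2))
    formatC(pi, format = "f", digits = 3)
  }, character(1))
}
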