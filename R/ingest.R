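# Reading, validating and writing expression and phenotype tables.
#
# An expression table is a wide tibble: `probe_id`, optional `gene` and
# `chromosome` annotation columns, then one numeric column per sample.
# Whether values are on the log2 scale is tracked in the "is_log2" attribute
# (set by read_expression / log2_transform and preserved by the package's
# own functions).

EXPR_ANNOT_COLS <- c("probe_id", "gene", "chromosome")

expr_sample_ids <- function(expr) setdiff(names(expr), EXPR_ANNOT_COLS)

expr_matrix <- function(expr) {
  ids <- expr_sample_ids(expr)
  m <- as.matrix(expr[ids])
  rownames(m) <- expr$probe_id
  m
}

expr_replace_values <- function(expr, m) {
  ids <- expr_sample_ids(expr)
  stopifnot(identical(dim(m), c(nrow(expr), length(ids))))
  expr[ids] <- as.data.frame(m)
  expr
}

#' Is an expression table on the log2 scale?
#' @param expr An expression tibble.
#' @return Logical flag (`FALSE` when never set).
#' @export
expression_is_log2 <- function(expr) isTRUE(attr(expr, "is_log2"))

set_log2_flag <- function(expr, flag) {
  attr(expr, "is_log2") <- isTRUE(flag)
  expr
}

validate_expression <- function(expr, context = "expression table") {
  if (!"probe_id" %in% names(expr)) abort(sprintf("%s lacks a probe_id column", context))
  dup <- expr$probe_id[duplicated(expr$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s has duplicate probe_id(s): %s", context,
                  paste(unique(dup), collapse = ", ")))
  }
  ids <- expr_sample_ids(expr)
  if (length(ids) == 0) abort(sprintf("%s has no sample columns", context))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("%s has repeated sample column(s): %s", context,
                  paste(unique(dup), collapse = ", ")))
  }
  for (id in ids) {
    col <- expr[[id]]
    if (!is.numeric(col)) {
      abort(sprintf("%s: column '%s' is not numeric", context, id))
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      abort(sprintf("%s: missing or non-finite intensity at probe '%s', sample '%s'",
                    context, expr$probe_id[bad[1]], id))
    }
  }
  invisible(expr)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row with `probe_id`, optional `gene` and `chromosome`
#' columns, then one numeric column per sample. Duplicate probe or sample
#' identifiers, non-numeric intensities and missing entries are rejected with
#' the offending coordinates named.
#'
#' @param path Path to a TSV file.
#' @param is_log2 Whether the stored values are already log2-scale.
#' @return An expression tibble.
#' @export
read_expression <- function(path, is_log2 = FALSE) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  dup <- hdr[duplicated(hdr)]
  if (length(dup) > 0) {
    abort(sprintf("expression file %s has repeated column(s): %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  sample_cols <- setdiff(hdr, EXPR_ANNOT_COLS)
  types <- c(
    setNames(rep(list(readr::col_character()), sum(hdr %in% EXPR_ANNOT_COLS)),
             intersect(hdr, EXPR_ANNOT_COLS)),
    setNames(rep(list(readr::col_double()), length(sample_cols)), sample_cols)
  )
  expr <- readr::read_tsv(path, col_types = do.call(readr::cols, types),
                          progress = FALSE)
  prob <- readr::problems(expr)
  if (nrow(prob) > 0) {
    abort(sprintf("expression file %s: non-numeric intensity at row %d, column %d",
                  path, prob$row[1], prob$col[1]))
  }
  expr <- validate_expression(expr, sprintf("expression file %s", path))
  set_log2_flag(expr, is_log2)
}

#' Write an expression table to TSV
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

validate_phenotype <- function(pheno, context = "phenotype table") {
  required <- c("sample_id", "outcome", "gleason")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks column(s): %s", context, paste(missing_cols, collapse = ", ")))
  }
  dup <- pheno$sample_id[duplicated(pheno$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s has duplicate sample_id(s): %s", context,
                  paste(unique(dup), collapse = ", ")))
  }
  check_levels <- function(col, levels) {
    if (!col %in% names(pheno)) return(invisible(NULL))
    vals <- pheno[[col]]
    bad <- !(is.na(vals) | vals %in% levels)
    if (any(bad)) {
      abort(sprintf("%s: unknown %s label '%s' at sample '%s'", context, col,
                    vals[which(bad)[1]], pheno$sample_id[which(bad)[1]]))
    }
  }
  check_levels("outcome", outcome_levels())
  check_levels("gleason", gleason_levels())
  check_levels("stage", stage_levels())
  check_levels("psa_cat", psa_levels())
  if ("replicate_of" %in% names(pheno)) {
    refs <- pheno$replicate_of[!is.na(pheno$replicate_of) & pheno$replicate_of != ""]
    absent <- setdiff(refs, pheno$sample_id)
    if (length(absent) > 0) {
      abort(sprintf("%s: replicate_of names absent sample(s): %s", context,
                    paste(absent, collapse = ", ")))
    }
  }
  invisible(pheno)
}

#' Read a tab-delimited phenotype table
#'
#' Required columns: `sample_id`, `outcome` (`nonrecurrent` /
#' `metastatic_lethal`), `gleason` (`leq6`, `g3p4`, `g4p3`, `g8to10`).
#' Optional: `stage` (`local`/`regional`/`missing`), `psa_cat`
#' (`lt4`/`c4to9`/`c10to19`/`ge20`/`missing`), `age`, `batch`,
#' `replicate_of`. Category labels are validated against these enumerations.
#'
#' @param path Path to a TSV file.
#' @return A phenotype tibble.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  pheno <- readr::read_tsv(path, col_types = readr::cols(
    age = readr::col_double(), .default = readr::col_character()
  ), progress = FALSE)
  validate_phenotype(pheno, sprintf("phenotype file %s", path))
  pheno
}

#' Write a phenotype table to TSV
#' @param pheno Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Align an expression table and a phenotype table
#'
#' Checks that every expression sample has exactly one phenotype row and
#' returns the phenotype reordered to the expression column order.
#'
#' @param expr Expression tibble.
#' @param pheno Phenotype tibble.
#' @return The reordered phenotype tibble.
#' @export
align_phenotype <- function(expr, pheno) {
  ids <- expr_sample_ids(expr)
  missing_ph <- setdiff(ids, pheno$sample_id)
  if (length(missing_ph) > 0) {
    abort(sprintf("no phenotype row for sample(s): %s",
                  paste(missing_ph, collapse = ", ")))
  }
  pheno[match(ids, pheno$sample_id), , drop = FALSE]
}
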