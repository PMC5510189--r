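# Shared fixture builders: everything is generated in code at test time.

# Minimal expression tibble from a probes x samples matrix.
make_expr <- function(m, probe_ids = sprintf("TX_%03d", seq_len(nrow(m))),
                      sample_ids = sprintf("S%02d", seq_len(ncol(m))),
                      is_log2 = TRUE) {
  df <- tibble::tibble(probe_id = probe_ids)
  vals <- as.data.frame(m)
  names(vals) <- sample_ids
  out <- dplyr::bind_cols(df, vals)
  attr(out, "is_log2") <- is_log2
  out
}

# Minimal phenotype for n0 controls then n1 cases.
make_pheno <- function(n0, n1, sample_ids = sprintf("S%02d", seq_len(n0 + n1)),
                       gleason = NULL, batch = NULL, seed = 99) {
  n <- n0 + n1
  outcome <- c(rep("nonrecurrent", n0), rep("metastatic_lethal", n1))
  if (is.null(gleason)) {
    gleason <- withr::with_seed(seed, c(
      sample(gleason_levels(), n0, replace = TRUE, prob = c(157, 93, 15, 13) / 278),
      sample(gleason_levels(), n1, replace = TRUE, prob = c(5, 11, 5, 6) / 27)
    ))
  }
  tibble::tibble(
    sample_id = sample_ids, outcome = outcome, gleason = gleason,
    stage = "local", psa_cat = "lt4",
    age = withr::with_seed(seed + 1, round(rnorm(n, 58, 7), 1)),
    batch = if (is.null(batch)) "batch1" else batch,
    replicate_of = NA_character_
  )
}

# Small seeded case-control cohort with one planted transcript among nulls.
make_planted_cohort <- function(n0 = 60, n1 = 25, n_null = 50, delta = 1.2,
                                sigma = 0.7, seed = 5) {
  withr::with_seed(seed, {
    n <- n0 + n1
    m <- matrix(rnorm((n_null + 1) * n, mean = 9, sd = sigma), n_null + 1, n)
    m[1, (n0 + 1):n] <- m[1, (n0 + 1):n] + delta
    expr <- make_expr(m)
    pheno <- make_pheno(n0, n1, seed = seed + 1)
    list(expr = expr, pheno = pheno, planted_id = expr$probe_id[1])
  })
}

# Phenotype reproducing the discovery-cohort Gleason margin counts
# (157/93/15/13 nonrecurrent vs 5/11/5/6 metastatic-lethal).
make_fh_gleason_pheno <- function() {
  gl <- c(rep(gleason_levels(), times = c(157, 93, 15, 13)),
          rep(gleason_levels(), times = c(5, 11, 5, 6)))
  make_pheno(278, 27, sample_ids = sprintf("P%03d", 1:305), gleason = gl)
}
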