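# Seeded two-cohort synthetic data generator with planted log2 effects.

#' Simulation configuration for the two-cohort study design
#'
#' Defaults emulate a population-based discovery cohort (278 nonrecurrent vs
#' 27 metastatic-lethal) with an independent validation set (46 vs 32),
#' 26,051 transcripts of which 48 carry planted log2 effects with magnitudes
#' 0.3-1.1 (about half up-regulated in cases), log2 baselines in 7-14,
#' residual SDs in 0.5-1.0, four plate batches with SD 0.2 offsets, and
#' Gleason category probabilities matching the observed outcome-conditional
#' distributions (so Gleason genuinely confounds the outcome).
#'
#' @param n_nonrecurrent_discovery,n_metlethal_discovery Discovery group sizes.
#' @param n_nonrecurrent_validation,n_metlethal_validation Validation group sizes.
#' @param n_transcripts Number of transcripts simulated.
#' @param n_planted Number of transcripts carrying a nonzero effect.
#' @param effect_range Length-2 vector: (low, high) |log2 effect| magnitudes.
#' @param frac_upregulated Proportion of planted effects positive in cases.
#' @param baseline_mean_range Length-2 vector of log2 baseline means.
#' @param residual_sd_range Length-2 vector of residual log2 SDs.
#' @param n_batches Number of plate batches (round-robin assignment).
#' @param batch_sd SD of the per-batch log2 offsets.
#' @param gleason_probs_nonrecurrent,gleason_probs_metlethal Probability
#'   4-vectors over Gleason categories (<=6, 3+4, 4+3, 8-10).
#' @param seed Integer seed; the full generator is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_nonrecurrent_discovery = 278,
                       n_metlethal_discovery = 27,
                       n_nonrecurrent_validation = 46,
                       n_metlethal_validation = 32,
                       n_transcripts = 26051,
                       n_planted = 48,
                       effect_range = c(0.3, 1.1),
                       frac_upregulated = 25 / 48,
                       baseline_mean_range = c(7, 14),
                       residual_sd_range = c(0.5, 1.0),
                       n_batches = 4,
                       batch_sd = 0.2,
                       gleason_probs_nonrecurrent = c(157, 93, 15, 13) / 278,
                       gleason_probs_metlethal = c(5, 11, 5, 6) / 27,
                       seed = 1L) {
  cfg <- list(
    n_nonrecurrent_discovery = n_nonrecurrent_discovery,
    n_metlethal_discovery = n_metlethal_discovery,
    n_nonrecurrent_validation = n_nonrecurrent_validation,
    n_metlethal_validation = n_metlethal_validation,
    n_transcripts = n_transcripts, n_planted = n_planted,
    effect_range = effect_range, frac_upregulated = frac_upregulated,
    baseline_mean_range = baseline_mean_range,
    residual_sd_range = residual_sd_range,
    n_batches = n_batches, batch_sd = batch_sd,
    gleason_probs_nonrecurrent = gleason_probs_nonrecurrent,
    gleason_probs_metlethal = gleason_probs_metlethal,
    seed = as.integer(seed)
  )
  counts <- c("n_nonrecurrent_discovery", "n_metlethal_discovery",
              "n_nonrecurrent_validation", "n_metlethal_validation",
              "n_transcripts", "n_batches")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("invariant violated: %s must be >= 1", nm))
  }
  if (n_planted < 0 || n_planted > n_transcripts) {
    abort("invariant violated: 0 <= n_planted <= n_transcripts")
  }
  for (nm in c("gleason_probs_nonrecurrent", "gleason_probs_metlethal")) {
    p <- cfg[[nm]]
    if (length(p) != 4 || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("invariant violated: %s must be a probability 4-vector summing to 1", nm))
    }
  }
  if (length(effect_range) != 2 || effect_range[1] > effect_range[2] ||
      any(effect_range < 0)) {
    abort("invariant violated: effect_range must satisfy 0 <= low <= high")
  }
  if (frac_upregulated < 0 || frac_upregulated > 1) {
    abort("invariant violated: frac_upregulated must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# Transcript-level parameters are drawn under the config seed alone, so the
# discovery and validation cohorts share the same truth (same planted set,
# signs and magnitudes) and the same per-transcript baselines and SDs.
sim_transcript_params <- function(config) {
  g <- config$n_transcripts
  withr::with_seed(config$seed, {
    mu <- runif(g, config$baseline_mean_range[1], config$baseline_mean_range[2])
    sigma <- runif(g, config$residual_sd_range[1], config$residual_sd_range[2])
    delta <- numeric(g)
    if (config$n_planted > 0) {
      planted <- sample.int(g, config$n_planted)
      mag <- runif(config$n_planted, config$effect_range[1], config$effect_range[2])
      sign <- ifelse(runif(config$n_planted) < config$frac_upregulated, 1, -1)
      delta[planted] <- sign * mag
    }
    list(mu = mu, sigma = sigma, delta = delta)
  })
}

#' Simulate one cohort of the two-cohort design
#'
#' Per transcript g and sample i, log2 expression is
#' `mu_g + delta_g * 1[case i] + b_batch(i) + eps`, `eps ~ N(0, sigma_g^2)`.
#' Gleason category is drawn conditionally on outcome from the configured
#' probability vectors; batches are assigned round-robin. The discovery and
#' validation cohorts share the transcript-level truth (planted set, signed
#' effects, baselines, SDs) but draw fresh samples; everything is
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param which `"discovery"` or `"validation"`.
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (expression tibble, log2-scale), `phenotype` (phenotype tibble) and
#'   `truth` (tibble: `transcript_id`, `delta`, `planted`).
#' @export
simulate_cohort <- function(config, which = c("discovery", "validation")) {
  which <- match.arg(which)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  par <- sim_transcript_params(config)
  g <- config$n_transcripts
  n0 <- config[[paste0("n_nonrecurrent_", which)]]
  n1 <- config[[paste0("n_metlethal_", which)]]
  n <- n0 + n1
  prefix <- if (which == "discovery") "D" else "V"
  probe_id <- sprintf("TX_%05d", seq_len(g))
  gene <- sprintf("GENE%05d", seq_len(g))
  chromosome <- rep(c(as.character(1:22), "X"), length.out = g)
  sample_id <- sprintf("%s%03d", prefix, seq_len(n))
  outcome <- c(rep("nonrecurrent", n0), rep("metastatic_lethal", n1))
  batch <- paste0("batch", rep_len(seq_len(config$n_batches), n))

  cohort_seed <- derive_seed(config$seed, paste0("cohort_", which))
  sim <- withr::with_seed(cohort_seed, {
    gl <- character(n)
    gl[outcome == "nonrecurrent"] <-
      sample(gleason_levels(), n0, replace = TRUE,
             prob = config$gleason_probs_nonrecurrent)
    gl[outcome == "metastatic_lethal"] <-
      sample(gleason_levels(), n1, replace = TRUE,
             prob = config$gleason_probs_metlethal)
    stage <- ifelse(runif(n) < ifelse(outcome == "nonrecurrent", 0.77, 0.48),
                    "local", "regional")
    psa <- c(
      sample(psa_levels(), n0, replace = TRUE,
             prob = c(47, 174, 30, 11, 16) / 278),
      sample(psa_levels(), n1, replace = TRUE,
             prob = c(2, 7, 6, 8, 4) / 27)
    )
    age <- round(rnorm(n, 58.2, 6.9), 1)
    b_off <- rnorm(config$n_batches, 0, config$batch_sd)
    case <- as.numeric(outcome == "metastatic_lethal")
    m <- par$mu + outer(par$delta, case) +
      matrix(rep(b_off[rep_len(seq_len(config$n_batches), n)], each = g), g, n) +
      matrix(rnorm(g * n, 0, par$sigma), g, n)
    list(gleason = gl, stage = stage, psa = psa, age = age, m = m)
  })

  expression <- tibble::tibble(probe_id = probe_id, gene = gene,
                               chromosome = chromosome)
  vals <- as.data.frame(sim$m)
  names(vals) <- sample_id
  expression <- set_log2_flag(dplyr::bind_cols(expression, vals), TRUE)

  phenotype <- tibble::tibble(
    sample_id = sample_id, outcome = outcome, gleason = sim$gleason,
    stage = sim$stage, psa_cat = sim$psa, age = sim$age, batch = batch,
    replicate_of = NA_character_
  )
  truth <- tibble::tibble(transcript_id = probe_id, delta = par$delta,
                          planted = as.integer(par$delta != 0))
  structure(list(expression = expression, phenotype = phenotype, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort as plain-text fixtures
#'
#' Writes `expression.tsv`, `phenotype.tsv` and `truth.tsv` into `directory`
#' (created if needed); the files round-trip losslessly through
#' [read_expression()] / [read_phenotype()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory.
#' @return A manifest tibble with one row per written file.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) abort(sprintf("cannot create directory: %s", directory))
  paths <- c(expression = file.path(directory, "expression.tsv"),
             phenotype = file.path(directory, "phenotype.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_expression(cohort$expression, paths[["expression"]])
  write_phenotype(cohort$phenotype, paths[["phenotype"]])
  readr::write_tsv(cohort$truth, paths[["truth"]], progress = FALSE)
  tibble::tibble(
    file = names(paths), path = unname(paths),
    rows = c(nrow(cohort$expression), nrow(cohort$phenotype), nrow(cohort$truth))
  )
}
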