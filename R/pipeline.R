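# Pipeline orchestration: staged runs with TSV artifacts between stages,
# a JSON run manifest, and deterministic stage seeding.

#' Pipeline configuration
#'
#' Collects the paths, preprocessing choices and stage parameters of a full
#' discovery-validation run. Input can be existing TSV files or a `simulate`
#' block (arguments to [sim_config()]), in which case the `simulate` stage
#' writes the input fixtures first. All stage seeds are derived
#' deterministically from the single global `seed`.
#'
#' @param out_dir Output directory for all artifacts.
#' @param expression,phenotype Discovery-cohort TSV paths (ignored when
#'   `simulate` is given).
#' @param expression_validation,phenotype_validation Validation-cohort TSV paths.
#' @param probe_keep_list Optional path to a probe keep-list.
#' @param expression_log2 Whether input expression values are already log2.
#' @param log2_offset Offset for [log2_transform()] when input is raw.
#' @param simulate Optional list of [sim_config()] arguments.
#' @param top_pauc_fraction,top_auc_fraction,combine_rule Screening settings.
#' @param specificity_floor,n_permutations,n_bootstrap ROC inference settings.
#' @param min_pauc_gain,min_auc_gain,max_wald_p,n_stability,min_count,max_panel_size,gleason_coding
#'   Selection settings (see [selection_config()]).
#' @param alpha,fdr_threshold Validation declaration thresholds.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            expression = NULL, phenotype = NULL,
                            expression_validation = NULL,
                            phenotype_validation = NULL,
                            probe_keep_list = NULL,
                            expression_log2 = FALSE, log2_offset = 0,
                            simulate = NULL,
                            top_pauc_fraction = 0.04, top_auc_fraction = 0.01,
                            combine_rule = "union",
                            specificity_floor = 0.95, n_permutations = 10000,
                            n_bootstrap = 2000,
                            min_pauc_gain = 0.0005, min_auc_gain = 0.005,
                            max_wald_p = 0.05, n_stability = 1000,
                            min_count = 40, max_panel_size = 10,
                            gleason_coding = "ordinal",
                            alpha = 0.05, fdr_threshold = 0.20,
                            seed = 1L) {
  for (nm in c("alpha", "fdr_threshold", "specificity_floor",
               "top_pauc_fraction", "top_auc_fraction")) {
    v <- get(nm)
    if (!(v > 0 && v <= 1)) abort(sprintf("invalid config field: %s must be in (0, 1]", nm))
  }
  cfg <- list(
    out_dir = out_dir, expression = expression, phenotype = phenotype,
    expression_validation = expression_validation,
    phenotype_validation = phenotype_validation,
    probe_keep_list = probe_keep_list,
    expression_log2 = isTRUE(expression_log2), log2_offset = log2_offset,
    simulate = simulate,
    top_pauc_fraction = top_pauc_fraction,
    top_auc_fraction = top_auc_fraction, combine_rule = combine_rule,
    specificity_floor = specificity_floor,
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    min_pauc_gain = min_pauc_gain, min_auc_gain = min_auc_gain,
    max_wald_p = max_wald_p, n_stability = as.integer(n_stability),
    min_count = as.integer(min_count),
    max_panel_size = as.integer(max_panel_size),
    gleason_coding = gleason_coding,
    alpha = alpha, fdr_threshold = fdr_threshold, seed = as.integer(seed)
  )
  if (is.null(cfg$simulate) &&
      (is.null(cfg$expression) || is.null(cfg$phenotype))) {
    abort("invalid config: either simulate or expression+phenotype paths are required")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(bad) > 0) {
    abort(sprintf("invalid config field: %s", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

pipeline_paths <- function(config) {
  out <- config$out_dir
  inp <- if (!is.null(config$simulate)) {
    list(expression = file.path(out, "input", "discovery", "expression.tsv"),
         phenotype = file.path(out, "input", "discovery", "phenotype.tsv"),
         expression_validation = file.path(out, "input", "validation", "expression.tsv"),
         phenotype_validation = file.path(out, "input", "validation", "phenotype.tsv"))
  } else {
    config[c("expression", "phenotype", "expression_validation",
             "phenotype_validation")]
  }
  c(inp, list(
    prep_expression = file.path(out, "preprocessed_discovery_expression.tsv"),
    prep_expression_validation = file.path(out, "preprocessed_validation_expression.tsv"),
    screen = file.path(out, "screen.tsv"),
    stability = file.path(out, "stability.tsv"),
    validation = file.path(out, "validation.tsv"),
    model_comparison = file.path(out, "model_comparison.tsv"),
    descriptive_discovery = file.path(out, "descriptive_discovery.tsv"),
    descriptive_validation = file.path(out, "descriptive_validation.tsv"),
    manifest = file.path(out, "manifest.json"),
    log = file.path(out, "run.log")
  ))
}

pipeline_log <- function(config, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  message(line)
  log_path <- file.path(config$out_dir, "run.log")
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' needs missing upstream artifact: %s", stage, path))
  }
  path
}

update_manifest <- function(config, paths, counts, artifacts) {
  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  } else {
    list(inputs = list(), counts = list(), artifacts = character())
  }
  manifest$seed <- config$seed
  manifest$config_hash <- rlang::hash(unclass(config))
  manifest$inputs <- paths[c("expression", "phenotype",
                             "expression_validation", "phenotype_validation")]
  manifest$counts <- utils::modifyList(as.list(manifest$counts), counts)
  manifest$artifacts <- sort(unique(c(unlist(manifest$artifacts), artifacts)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

preprocess_one <- function(config, expr_path, pheno_path, out_path, label) {
  expr <- read_expression(expr_path, is_log2 = config$expression_log2)
  pheno <- read_phenotype(pheno_path)
  n_in <- nrow(expr)
  if (!is.null(config$probe_keep_list)) {
    expr <- filter_probes(expr, read_keep_list(config$probe_keep_list))
  }
  if (!expression_is_log2(expr)) {
    expr <- quantile_normalize(expr)
    expr <- log2_transform(expr, offset = config$log2_offset)
  }
  batch_ok <- "batch" %in% names(pheno) &&
    length(unique(pheno$batch)) >= 2 && all(table(pheno$batch) >= 2)
  if (batch_ok) {
    expr <- batch_adjust(expr, pheno)
  } else {
    pipeline_log(config, "INFO",
                 sprintf("%s: batch adjustment skipped (fewer than 2 usable batches)", label))
  }
  if ("replicate_of" %in% names(pheno) &&
      any(!is.na(pheno$replicate_of) & nzchar(pheno$replicate_of))) {
    qc <- replicate_qc(expr, pheno)
    pipeline_log(config, "INFO", sprintf(
      "%s: replicate QC on %d pair(s), min correlation %.3f", label, nrow(qc),
      min(qc$correlation)))
  }
  write_expression(expr, out_path)
  list(n_in = n_in, n_out = nrow(expr))
}

#' Run the pipeline
#'
#' Executes the requested stage (or `"all"`): `simulate` writes synthetic
#' input fixtures; `preprocess` filters, normalizes, log2-transforms and
#' batch-adjusts both cohorts; `screen` ranks discovery transcripts by
#' AUC/pAUC; `select` runs bootstrap stability selection on the screened
#' candidates; `validate` evaluates robust markers in the validation cohort
#' and fits the Gleason-combined models; `report` writes descriptive tables.
#' Each stage reads its predecessor's TSV artifacts and updates a JSON run
#' manifest (seed, config hash, funnel counts, artifact list). A rerun with
#' the same configuration and inputs reproduces the TSV outputs
#' byte-identically.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param stage One of `"all"`, `"simulate"`, `"preprocess"`, `"screen"`,
#'   `"select"`, `"validate"`, `"report"`.
#' @return The manifest (invisibly) as a list.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "preprocess",
                                           "screen", "select", "validate",
                                           "report")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(config)
  stages <- if (stage == "all") {
    c(if (!is.null(config$simulate)) "simulate", "preprocess", "screen",
      "select", "validate", "report")
  } else {
    stage
  }

  for (st in stages) {
    pipeline_log(config, "INFO", sprintf("stage %s started", st))
    switch(st,
      simulate = {
        if (is.null(config$simulate)) abort("config has no simulate block")
        sim_args <- config$simulate
        sim_args$seed <- derive_seed(config$seed, "simulate")
        scfg <- do.call(sim_config, sim_args)
        man_d <- write_fixture(simulate_cohort(scfg, "discovery"),
                               dirname(paths$expression))
        man_v <- write_fixture(simulate_cohort(scfg, "validation"),
                               dirname(paths$expression_validation))
        update_manifest(config, paths,
                        list(n_transcripts_simulated = scfg$n_transcripts),
                        c(man_d$path, man_v$path))
      },
      preprocess = {
        require_artifact(paths$expression, st)
        require_artifact(paths$phenotype, st)
        res_d <- preprocess_one(config, paths$expression, paths$phenotype,
                                paths$prep_expression, "discovery")
        counts <- list(probes_in = res_d$n_in, probes_kept = res_d$n_out)
        arts <- paths$prep_expression
        if (!is.null(paths$expression_validation)) {
          require_artifact(paths$expression_validation, st)
          require_artifact(paths$phenotype_validation, st)
          preprocess_one(config, paths$expression_validation,
                         paths$phenotype_validation,
                         paths$prep_expression_validation, "validation")
          arts <- c(arts, paths$prep_expression_validation)
        }
        update_manifest(config, paths, counts, arts)
      },
      screen = {
        expr <- read_expression(require_artifact(paths$prep_expression, st),
                                is_log2 = TRUE)
        pheno <- read_phenotype(paths$phenotype)
        scr <- screen_transcripts(expr, pheno,
                                  top_pauc_fraction = config$top_pauc_fraction,
                                  top_auc_fraction = config$top_auc_fraction,
                                  combine_rule = config$combine_rule,
                                  specificity_floor = config$specificity_floor)
        readr::write_tsv(tibble::as_tibble(scr), paths$screen, progress = FALSE)
        update_manifest(config, paths,
                        list(transcripts_screened = nrow(scr),
                             transcripts_selected = sum(scr$selected)),
                        paths$screen)
      },
      select = {
        scr <- readr::read_tsv(require_artifact(paths$screen, st),
                               show_col_types = FALSE)
        expr <- read_expression(paths$prep_expression, is_log2 = TRUE)
        pheno <- read_phenotype(paths$phenotype)
        sel_cfg <- selection_config(
          min_pauc_gain = config$min_pauc_gain,
          min_auc_gain = config$min_auc_gain,
          max_wald_p = config$max_wald_p, n_stability = config$n_stability,
          min_count = config$min_count,
          max_panel_size = config$max_panel_size,
          gleason_coding = config$gleason_coding,
          seed = derive_seed(config$seed, "selection")
        )
        stab <- stability_select(expr, pheno,
                                 scr$transcript_id[scr$selected], sel_cfg)
        readr::write_tsv(tibble::as_tibble(stab), paths$stability, progress = FALSE)
        update_manifest(config, paths,
                        list(transcripts_robust = sum(stab$robust)),
                        paths$stability)
      },
      validate = {
        stab <- readr::read_tsv(require_artifact(paths$stability, st),
                                show_col_types = FALSE)
        scr <- readr::read_tsv(require_artifact(paths$screen, st),
                               show_col_types = FALSE)
        expr_v <- read_expression(
          require_artifact(paths$prep_expression_validation, st), is_log2 = TRUE)
        pheno_v <- read_phenotype(paths$phenotype_validation)
        panel <- dplyr::inner_join(
          dplyr::filter(stab, .data$robust)["transcript_id"],
          scr[, c("transcript_id", "orientation")], by = "transcript_id")
        if (nrow(panel) == 0) {
          pipeline_log(config, "WARN", "no robust transcripts to validate")
          update_manifest(config, paths, list(transcripts_validated = 0),
                          character())
        } else {
          rcfg <- roc_config(specificity_floor = config$specificity_floor,
                             n_permutations = config$n_permutations,
                             n_bootstrap = config$n_bootstrap,
                             seed = derive_seed(config$seed, "validation"))
          val <- validate_panel(expr_v, pheno_v, panel, rcfg,
                                alpha = config$alpha,
                                fdr_threshold = config$fdr_threshold)
          cmb <- combined_model(expr_v, pheno_v, panel$transcript_id,
                                gleason_coding = config$gleason_coding,
                                specificity_floor = config$specificity_floor)
          readr::write_tsv(tibble::as_tibble(val), paths$validation, progress = FALSE)
          readr::write_tsv(cmb, paths$model_comparison, progress = FALSE)
          update_manifest(config, paths,
                          list(transcripts_validated = sum(val$validated)),
                          c(paths$validation, paths$model_comparison))
        }
      },
      report = {
        pheno <- read_phenotype(require_artifact(paths$phenotype, st))
        readr::write_tsv(descriptive_table(pheno), paths$descriptive_discovery,
                         progress = FALSE)
        arts <- paths$descriptive_discovery
        if (!is.null(paths$phenotype_validation) &&
            file.exists(paths$phenotype_validation)) {
          readr::write_tsv(descriptive_table(read_phenotype(paths$phenotype_validation)),
                           paths$descriptive_validation, progress = FALSE)
          arts <- c(arts, paths$descriptive_validation)
        }
        update_manifest(config, paths, list(), arts)
      }
    )
    pipeline_log(config, "INFO", sprintf("stage %s done", st))
  }
  invisible(jsonlite::read_json(paths$manifest, simplifyVector = TRUE))
}
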