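# Forward transcript selection over the Gleason base model, and its
# bootstrap-stabilized version.

#' Configuration for forward and stability selection
#'
#' Defaults follow the three stopping criteria of the model-building stage:
#' a step must raise the model pAUC by at least 0.0005 (pAUC criterion), the
#' AUC by at least 0.005 (AUC criterion), or add a term with Wald p <= 0.05
#' (Wald criterion); selection is repeated on 1000 bootstrap resamples and a
#' transcript is "robust" when it appears more than 40 times in at least one
#' criterion's panels.
#'
#' @param min_pauc_gain Minimum model pAUC increase to continue (default 0.0005).
#' @param min_auc_gain Minimum model AUC increase to continue (default 0.005).
#' @param max_wald_p Largest admissible Wald p for a new term (default 0.05).
#' @param n_stability Number of bootstrap resamples (default 1000).
#' @param min_count Strict count threshold for robustness (default 40).
#' @param max_panel_size Cap on panel length per run (default 10), guarding
#'   against degenerate long panels on resamples.
#' @param gleason_coding Base-model Gleason coding: `"ordinal"` (1-4, default;
#'   keeps the base model estimable with few events) or `"categorical"`.
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(min_pauc_gain = 0.0005, min_auc_gain = 0.005,
                             max_wald_p = 0.05, n_stability = 1000,
                             min_count = 40, max_panel_size = 10,
                             gleason_coding = c("ordinal", "categorical"),
                             seed = 1L) {
  gleason_coding <- match.arg(gleason_coding)
  if (min_pauc_gain <= 0 || min_auc_gain <= 0 || max_wald_p <= 0) {
    abort("selection thresholds must be positive")
  }
  if (min_count >= n_stability) abort("min_count must be < n_stability")
  structure(
    list(min_pauc_gain = min_pauc_gain, min_auc_gain = min_auc_gain,
         max_wald_p = max_wald_p, n_stability = as.integer(n_stability),
         min_count = as.integer(min_count),
         max_panel_size = as.integer(max_panel_size),
         gleason_coding = gleason_coding, seed = as.integer(seed)),
    class = "selection_config"
  )
}

auc_of_scores <- function(scores, y, n1, n0, const) {
  (sum(rank(scores)[y == 1]) - const) / (n1 * n0)
}

# Forward selection given prebuilt matrices. E: candidates x samples matrix
# (rownames = transcript ids); base_design: samples x k base covariates.
# The compiled engine ("cpp") is the default; the plain-R engine defines the
# reference semantics and backs the agreement tests.
forward_select_core <- function(E, base_design, y, criterion, cfg, fmax = 0.05,
                                engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    code <- match(criterion, c("auc", "pauc", "wald")) - 1L
    res <- .forward_select_cpp(E, base_design, as.numeric(y), code,
                               cfg$min_auc_gain, cfg$min_pauc_gain,
                               cfg$max_wald_p, cfg$max_panel_size, fmax)
    if (!isTRUE(res$base_ok)) {
      return(list(panel = character(0), steps = NULL, base_ok = FALSE,
                  base_auc = NA_real_, base_pauc = NA_real_))
    }
    ids <- rownames(E)[res$panel]
    steps <- if (length(ids) > 0) {
      tibble::tibble(step = seq_along(ids), transcript_id = ids,
                     metric = res$metric, gain = res$gain, wald_p = res$wald_p)
    } else {
      NULL
    }
    return(list(panel = ids, steps = steps, base_ok = TRUE,
                base_auc = res$base_auc, base_pauc = res$base_pauc))
  }
  forward_select_core_r(E, base_design, y, criterion, cfg, fmax)
}

forward_select_core_r <- function(E, base_design, y, criterion, cfg, fmax = 0.05) {
  n1 <- sum(y)
  n0 <- length(y) - n1
  const <- n1 * (n1 + 1) / 2
  X <- cbind(1, base_design)
  base_fit <- logit_irls(X, y)
  if (!base_fit$ok || !base_fit$converged) {
    return(list(panel = character(0), steps = NULL, base_ok = FALSE,
                base_auc = NA_real_, base_pauc = NA_real_))
  }
  metric_of <- function(fitted) {
    switch(criterion,
           auc = auc_of_scores(fitted, y, n1, n0, const),
           pauc = roc_pauc(fitted, y, 1 - fmax),
           wald = NA_real_)
  }
  base_auc <- auc_of_scores(base_fit$fitted, y, n1, n0, const)
  base_pauc <- roc_pauc(base_fit$fitted, y, 1 - fmax)
  cur_metric <- if (criterion == "wald") NA_real_ else metric_of(base_fit$fitted)
  beta_cur <- base_fit$beta
  remaining <- seq_len(nrow(E))
  panel <- integer(0)
  steps <- list()

  while (length(panel) < cfg$max_panel_size && length(remaining) > 0) {
    best <- NULL
    for (j in remaining) {
      Xc <- cbind(X, E[j, ])
      # candidate evaluation uses a slightly looser tolerance than the final
      # fits: metric gains are compared at the 1e-3 scale
      fit <- logit_irls(Xc, y, beta_start = c(beta_cur, 0),
                        max_iter = 30, tol = 1e-6)
      if (!fit$ok || !fit$converged) next
      if (criterion == "wald") {
        if (fit$aliased[ncol(Xc)]) next # redundant term: no Wald statistic
        keep <- !fit$aliased
        vc <- tryCatch(solve(fit$info[keep, keep, drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(vc)) next
        se <- sqrt(max(vc[nrow(vc), nrow(vc)], 0))
        if (se == 0) next
        p <- 2 * pnorm(-abs(fit$beta[ncol(Xc)] / se))
        if (is.null(best) || p < best$value) {
          best <- list(j = j, value = p, fit = fit)
        }
      } else {
        v <- metric_of(fit$fitted)
        if (is.null(best) || v > best$value) {
          best <- list(j = j, value = v, fit = fit)
        }
      }
    }
    if (is.null(best)) break # all candidate fits failed
    if (criterion == "wald") {
      if (best$value > cfg$max_wald_p) break
      gain <- NA_real_
    } else {
      gain <- best$value - cur_metric
      threshold <- if (criterion == "auc") cfg$min_auc_gain else cfg$min_pauc_gain
      if (gain < threshold) break
      cur_metric <- best$value
    }
    panel <- c(panel, best$j)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(panel), transcript_id = rownames(E)[best$j],
      metric = if (criterion == "wald") NA_real_ else best$value,
      gain = gain,
      wald_p = if (criterion == "wald") best$value else NA_real_
    )
    X <- cbind(X, E[best$j, ])
    beta_cur <- best$fit$beta
    remaining <- setdiff(remaining, best$j)
  }
  list(panel = rownames(E)[panel],
       steps = if (length(steps)) dplyr::bind_rows(steps) else NULL,
       base_ok = TRUE, base_auc = base_auc, base_pauc = base_pauc)
}

prepare_selection_inputs <- function(expr, pheno, candidates, cfg) {
  validate_expression(expr)
  pheno <- align_phenotype(expr, pheno)
  y <- as_binary_labels(pheno$outcome)
  check_two_classes(y)
  if (length(candidates) == 0) abort("candidates must be nonempty")
  absent <- setdiff(candidates, expr$probe_id)
  if (length(absent) > 0) {
    abort(sprintf("candidate transcript(s) absent from expression: %s",
                  paste(head(absent, 5), collapse = ", ")))
  }
  m <- expr_matrix(expr)
  E <- m[candidates, , drop = FALSE]
  base <- gleason_design(pheno$gleason, cfg$gleason_coding)
  list(E = E, base = base, y = y)
}

#' Forward transcript selection over the Gleason base model
#'
#' Starting from the Gleason-only logistic model, each step fits every
#' remaining candidate added singly and keeps the one maximizing the
#' criterion's figure of merit: model pAUC gain, model AUC gain (both
#' computed on in-sample fitted probabilities), or the smallest Wald p of
#' the new term. Selection stops when the criterion's stopping rule fires
#' (gain below `min_pauc_gain`/`min_auc_gain`, or Wald p above `max_wald_p`)
#' or the panel cap is reached. Candidates whose fits fail to converge
#' (including perfect separation) are skipped. Deterministic given the data
#' and configuration.
#'
#' @param expr Expression tibble (log2 scale).
#' @param pheno Phenotype tibble with `outcome` and `gleason`.
#' @param candidates Character vector of candidate transcript identifiers.
#' @param criterion `"auc"`, `"pauc"` or `"wald"`.
#' @param cfg A [selection_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both give the same selections.
#' @return A tibble of class `forward_panel` (possibly zero rows) with
#'   columns `step`, `transcript_id`, `metric`, `gain`, `wald_p`;
#'   attributes carry the criterion and base-model AUC/pAUC.
#' @export
forward_select <- function(expr, pheno, candidates,
                           criterion = c("auc", "pauc", "wald"),
                           cfg = selection_config(), engine = c("cpp", "r")) {
  criterion <- match.arg(criterion)
  engine <- match.arg(engine)
  inp <- prepare_selection_inputs(expr, pheno, candidates, cfg)
  res <- forward_select_core(inp$E, inp$base, inp$y, criterion, cfg,
                             engine = engine)
  if (!res$base_ok) abort("base Gleason model did not converge")
  out <- if (is.null(res$steps)) {
    tibble::tibble(step = integer(), transcript_id = character(),
                   metric = numeric(), gain = numeric(), wald_p = numeric())
  } else {
    res$steps
  }
  structure(out, class = c("forward_panel", class(out)),
            criterion = criterion, base_auc = res$base_auc,
            base_pauc = res$base_pauc)
}

#' @rdname forward_select
#' @param x A `forward_panel`.
#' @param ... Unused.
#' @export
glance.forward_panel <- function(x, ...) {
  tibble::tibble(
    criterion = attr(x, "criterion"),
    panel_size = nrow(x),
    base_auc = attr(x, "base_auc"),
    base_pauc = attr(x, "base_pauc"),
    final_metric = if (nrow(x) > 0) x$metric[nrow(x)] else NA_real_
  )
}

#' Bootstrap stability selection of transcripts
#'
#' Draws `n_stability` bootstrap resamples of the samples (stratified by
#' outcome, so every resample keeps both classes), reruns [forward_select()]
#' on each resample under each of the three criteria, and tallies how often
#' every candidate is selected. A transcript is flagged robust when its
#' count exceeds `min_count` under at least one criterion (strict
#' inequality). Fully seeded and deterministic.
#'
#' @inheritParams forward_select
#' @param criteria Criteria to tally (default all three).
#' @param bootstrap If `FALSE`, every "resample" is the full sample; with
#'   `n_stability = 1` this reproduces a single [forward_select()] run.
#' @return A tibble of class `stability_result`: `transcript_id`,
#'   `count_auc`, `count_pauc`, `count_wald`, `max_count`, `robust`.
#' @export
stability_select <- function(expr, pheno, candidates, cfg = selection_config(),
                             criteria = c("auc", "pauc", "wald"),
                             bootstrap = TRUE, engine = c("cpp", "r")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  engine <- match.arg(engine)
  inp <- prepare_selection_inputs(expr, pheno, candidates, cfg)
  y <- inp$y
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  B <- cfg$n_stability
  resamples <- if (bootstrap) {
    withr::with_seed(derive_seed(cfg$seed, "stability"), {
      lapply(seq_len(B), function(b) {
        c(sample(idx0, replace = TRUE), sample(idx1, replace = TRUE))
      })
    })
  } else {
    lapply(seq_len(B), function(b) seq_along(y))
  }
  counts <- matrix(0L, nrow = length(candidates), ncol = 3,
                   dimnames = list(candidates, c("auc", "pauc", "wald")))
  n_failed_base <- 0L
  for (b in seq_len(B)) {
    idx <- resamples[[b]]
    Eb <- inp$E[, idx, drop = FALSE]
    baseb <- inp$base[idx, , drop = FALSE]
    yb <- y[idx]
    for (cr in criteria) {
      res <- forward_select_core(Eb, baseb, yb, cr, cfg, engine = engine)
      if (!res$base_ok) {
        n_failed_base <- n_failed_base + 1L
        next
      }
      if (length(res$panel) > 0) {
        counts[res$panel, cr] <- counts[res$panel, cr] + 1L
      }
    }
  }
  if (n_failed_base > 0) {
    inform(sprintf("base model failed on %d resample-criterion runs (skipped)",
                   n_failed_base))
  }
  out <- tibble::tibble(
    transcript_id = candidates,
    count_auc = counts[, "auc"],
    count_pauc = counts[, "pauc"],
    count_wald = counts[, "wald"]
  )
  out$max_count <- pmax(out$count_auc, out$count_pauc, out$count_wald)
  out$robust <- out$max_count > cfg$min_count
  structure(out, class = c("stability_result", class(out)),
            n_stability = B, min_count = cfg$min_count, criteria = criteria)
}
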