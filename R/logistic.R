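# Logistic regression by iteratively reweighted least squares, tuned for the
# many small fits of the forward-selection loops (warm starts, no model
# frames). stats::glm is the independent cross-check in the test suite.

# Core IRLS on a design matrix that already includes the intercept column.
# Returns minimal components; used in hot loops. Aliased (exactly collinear)
# columns get coefficient 0, so the fit equals the reduced model and a
# redundant covariate leaves the deviance unchanged.
logit_irls <- function(X, y, beta_start = NULL, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  # centre the non-intercept columns: identical fit, but keeps the intercept
  # near 0 so the coefficient-divergence separation check is scale-honest
  centres <- c(0, if (p > 1) colMeans(X[, -1, drop = FALSE]))
  X <- X - rep(centres, each = nrow(X))
  beta <- if (is.null(beta_start)) rep(0, p) else beta_start
  if (!is.null(beta_start) && p > 1) {
    beta[1] <- beta[1] + sum(centres[-1] * beta_start[-1])
  }
  dev_old <- Inf
  converged <- FALSE
  aliased <- rep(FALSE, p)
  it <- 0L
  w <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    zw <- w * eta + (y - mu) # X' W z with z the working response
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(X, zw))),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      # rank-deficient normal equations: pivoted WLS, aliased terms get 0
      sw <- sqrt(w)
      wls <- tryCatch(stats::lm.fit(X * sw, (eta + (y - mu) / w) * sw),
                      error = function(e) NULL)
      if (is.null(wls)) return(list(ok = FALSE, reason = "weighted least squares failed"))
      beta_new <- unname(wls$coefficients)
      aliased <- is.na(beta_new)
      beta_new[aliased] <- 0
    } else {
      aliased <- rep(FALSE, p)
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
    if (max(abs(beta)) > 30 || dev < 1e-6) {
      # diverging coefficient / vanishing deviance: separation; further
      # iterations only inflate the estimates
      dev_old <- dev
      break
    }
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  separated <- dev_old < 1e-6 || max(abs(beta)) > 30
  fitted <- 1 / (1 + exp(-drop(X %*% beta)))
  info <- crossprod(X, X * w)
  # translate back to the uncentred parameterisation
  if (p > 1) {
    beta_out <- beta
    beta_out[1] <- beta[1] - sum(centres[-1] * beta[-1])
    A <- diag(p)
    A[1, -1] <- -centres[-1]
    info_out <- tryCatch(solve(t(A), info %*% solve(A)), error = function(e) info)
  } else {
    beta_out <- beta
    info_out <- info
  }
  list(ok = TRUE, beta = beta_out, aliased = aliased, deviance = dev_old,
       fitted = fitted,
       converged = converged && !separated, separated = separated,
       info = info_out, iterations = it)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (convergence when the relative deviance change falls below `tol`,
#' at most `max_iter` iterations), with Wald statistics from the observed
#' information. Perfect separation (deviance collapsing toward 0 or a
#' diverging coefficient) is flagged via `converged = FALSE` and
#' `separated = TRUE`.
#'
#' @param design Covariate matrix or data frame (no intercept column; one is
#'   added), one row per sample.
#' @param outcome 0/1 vector (or outcome strings) per sample; both classes
#'   must be present.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `logit_fit` with coefficients, standard
#'   errors, fitted probabilities, deviance and convergence flags. Supports
#'   [tidy()] and [glance()].
#' @export
fit_logistic <- function(design, outcome, max_iter = 50, tol = 1e-8) {
  y <- as_binary_labels(outcome)
  check_two_classes(y)
  X <- cbind("(Intercept)" = 1, as.matrix(design))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- logit_irls(X, y, max_iter = max_iter, tol = tol)
  if (!fit$ok) abort(sprintf("logistic fit failed: %s", fit$reason))
  keep <- !fit$aliased
  vc <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  vc_sub <- tryCatch(solve(fit$info[keep, keep, drop = FALSE]),
                     error = function(e) NULL)
  if (!is.null(vc_sub)) vc[keep, keep] <- vc_sub
  se <- sqrt(pmax(diag(vc), 0))
  if (any(fit$aliased)) {
    warn(sprintf("aliased (collinear) term(s) dropped: %s",
                 paste(colnames(X)[fit$aliased], collapse = ", ")))
  }
  structure(
    list(coefficients = setNames(fit$beta, colnames(X)),
         std_errors = setNames(se, colnames(X)),
         aliased = setNames(fit$aliased, colnames(X)),
         vcov = vc, fitted = fit$fitted, deviance = fit$deviance,
         converged = fit$converged, separated = fit$separated,
         iterations = fit$iterations, n = length(y), y = y),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, deviance = %.3f, converged = %s\n",
              x$n, x$deviance, x$converged))
  print(round(rbind(estimate = x$coefficients, se = x$std_errors), 4))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logit_fit`.
#' @param ... Unused.
#' @export
tidy.logit_fit <- function(x, ...) {
  z <- x$coefficients / x$std_errors
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname fit_logistic
#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance,
    AIC = x$deviance + 2 * length(x$coefficients),
    df.residual = x$n - length(x$coefficients),
    n = x$n, converged = x$converged, separated = x$separated
  )
}

#' Likelihood-ratio test between two nested logistic fits
#'
#' @param fit_null,fit_alt `logit_fit` objects, `fit_null` nested in `fit_alt`.
#' @param df Degrees of freedom of the comparison (default: difference in
#'   number of coefficients).
#' @return A tibble with `lr_stat`, `df`, `p_value`.
#' @export
lr_test <- function(fit_null, fit_alt,
                    df = length(fit_alt$coefficients) - length(fit_null$coefficients)) {
  stat <- max(fit_null$deviance - fit_alt$deviance, 0)
  tibble::tibble(lr_stat = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE))
}
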