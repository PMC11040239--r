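#' Specify a (generalized) mixed model
#'
#' A light container describing the response, fixed effects and random-effect
#' structure of a model, independent of any particular data set. The response
#' is either a single binary column or a pair of columns holding aggregated
#' (successes, failures) counts -- the "two-column" binomial response used for
#' the sampling-matrix analysis.
#'
#' @param response a column name (binary 0/1 response) or a length-2
#'   character vector `c(successes, failures)`.
#' @param fixed_terms character vector of predictor column names; empty for
#'   an intercept-only model.
#' @param random_terms named list: names are grouping-factor columns, values
#'   are character vectors of slope columns (empty vector = random intercept
#'   only). Slope columns are normally a subset of `fixed_terms`; a slope
#'   without its fixed effect is permitted so that a reduced model in a
#'   likelihood-ratio test can stay "otherwise identical" to the full one.
#' @param family `"binomial"` (logit link) or `"beta"` (logit link).
#' @return an object of class `uds_model_spec`.
#' @export
#' @examples
#' model_spec("test_correct", random_terms = list(participant_id = character(),
#'                                                object_id = character()))
model_spec <- function(response, fixed_terms = character(),
                       random_terms = list(), family = "binomial") {
  stopifnot(is.character(response), length(response) %in% 1:2,
            is.character(fixed_terms))
  family <- match.arg(family, c("binomial", "beta"))
  if (length(random_terms)) {
    if (is.null(names(random_terms)) || any(!nzchar(names(random_terms)))) {
      stop("random_terms must be a named list (grouping factor -> slope columns)",
           call. = FALSE)
    }
    if (!all(vapply(random_terms, is.character, TRUE))) {
      stop("random_terms values must be character vectors of slope columns",
           call. = FALSE)
    }
  }
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_terms = random_terms, family = family),
            class = "uds_model_spec")
}

# Build the model formula string from a spec.
spec_formula <- function(spec) {
  lhs <- if (length(spec$response) == 2L) {
    sprintf("cbind(%s, %s)", spec$response[1], spec$response[2])
  } else {
    spec$response
  }
  fx <- if (length(spec$fixed_terms)) paste(spec$fixed_terms, collapse = " + ") else "1"
  re <- vapply(names(spec$random_terms), function(g) {
    slopes <- spec$random_terms[[g]]
    if (length(slopes)) sprintf("(1 + %s | %s)", paste(slopes, collapse = " + "), g)
    else sprintf("(1 | %s)", g)
  }, "")
  stats::as.formula(paste(lhs, "~", paste(c(fx, re), collapse = " + ")))
}

#' Fit a logistic mixed model (Laplace approximation)
#'
#' Maximizes the Laplace-approximated marginal likelihood over fixed effects
#' and variance components, with support for crossed random factors and for
#' both binary and aggregated two-column binomial responses. Estimation is
#' delegated to [lme4::glmer()]; with no random terms the model degenerates
#' to an ordinary logistic regression via [stats::glm()].
#'
#' Non-convergence never produces a silent wrong answer: the returned fit
#' carries `converged = FALSE`. A variance component on the zero boundary (or
#' a degenerate slope correlation) sets `singular = TRUE`, signalling a
#' non-identifiable term that callers typically drop and record. Apparent
#' separation or collinearity marks the affected terms in `non_estimable`.
#'
#' @param spec a [model_spec()].
#' @param table data.frame containing all referenced columns.
#' @param nAGQ passed to [lme4::glmer()]; 1 (default) is the Laplace
#'   approximation, 0 a faster penalized-likelihood step used inside
#'   permutation loops, and larger values select adaptive Gauss-Hermite
#'   quadrature (single random factor only).
#' @return an object of class `uds_fit`: named `estimates` and
#'   `standard_errors` on the link scale, `varcomps` (random-effect variances
#'   and slope covariances), `loglik`, `converged`, `singular`,
#'   `non_estimable`, `n_obs`, `n_groups`, and the underlying `model`.
#' @export
fit_logistic_mixed <- function(spec, table, nAGQ = 1L) {
  stopifnot(inherits(spec, "uds_model_spec"))
  if (spec$family != "binomial") stop("use fit_beta_glm() for the beta family", call. = FALSE)
  if (!is.data.frame(table) || nrow(table) == 0L) stop("table must be a nonempty data.frame", call. = FALSE)
  needed <- c(spec$response, spec$fixed_terms, names(spec$random_terms))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop(sprintf("column(s) %s not found in table",
                 paste(sQuote(missing_cols), collapse = ", ")), call. = FALSE)
  }
  for (g in names(spec$random_terms)) {
    if (length(unique(table[[g]])) < 2L) {
      stop(sprintf("grouping factor '%s' needs at least 2 levels", g), call. = FALSE)
    }
  }
  # a constant response is complete separation at the intercept: no finite
  # estimate exists, which is a flagged outcome rather than an error
  resp_const <- if (length(spec$response) == 1L) {
    stats::var(table[[spec$response]]) == 0
  } else {
    all(table[[spec$response[1]]] == 0) || all(table[[spec$response[2]]] == 0)
  }
  if (isTRUE(resp_const)) {
    terms_all <- c("(Intercept)", spec$fixed_terms)
    return(structure(list(
      estimates = stats::setNames(rep(NA_real_, length(terms_all)), terms_all),
      standard_errors = stats::setNames(rep(NA_real_, length(terms_all)), terms_all),
      varcomps = list(), loglik = NA_real_, converged = FALSE, singular = FALSE,
      non_estimable = terms_all, n_obs = nrow(table), n_groups = integer(),
      family = "binomial", spec = spec, model = NULL), class = "uds_fit"))
  }
  form <- spec_formula(spec)

  if (!length(spec$random_terms)) {
    fit <- stats::glm(form, family = stats::binomial(), data = table)
    return(as_uds_fit_glm(fit, spec))
  }

  msgs <- character()
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(form, data = table, family = stats::binomial(),
                                 nAGQ = nAGQ)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  as_uds_fit_mer(fit, spec, msgs)
}

as_uds_fit_mer <- function(fit, spec, msgs = character()) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  varcomps <- lapply(vc, function(m) {
    v <- diag(m)
    names(v) <- paste0("var_", rownames(m))
    v
  })
  conv_msgs <- fit@optinfo$conv$lme4$messages %||% character()
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", conv_msgs, ignore.case = TRUE)) &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  structure(list(
    estimates = est,
    standard_errors = stats::setNames(as.numeric(se), names(est)),
    varcomps = varcomps,
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    singular = lme4::isSingular(fit),
    non_estimable = flag_non_estimable(est, se),
    n_obs = stats::nobs(fit),
    n_groups = vapply(fit@flist, function(f) length(levels(f)), 0L),
    family = "binomial",
    spec = spec,
    model = fit
  ), class = "uds_fit")
}

as_uds_fit_glm <- function(fit, spec) {
  est <- stats::coef(fit)
  aliased <- names(est)[is.na(est)]
  est <- est[!is.na(est)]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[names(est)]
  structure(list(
    estimates = est,
    standard_errors = se,
    varcomps = list(),
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    singular = FALSE,
    non_estimable = unique(c(aliased, flag_non_estimable(est, se))),
    n_obs = stats::nobs(fit),
    n_groups = integer(),
    family = "binomial",
    spec = spec,
    model = fit
  ), class = "uds_fit")
}

# Heuristic separation flag: an essentially infinite logit estimate with a
# blown-up standard error means the term is not estimable from these data.
flag_non_estimable <- function(est, se) {
  names(est)[(abs(est) > 10 & se > 25) | !is.finite(se)]
}

#' @export
print.uds_fit <- function(x, ...) {
  cat(sprintf("<uds_fit> %s, logLik = %.3f, converged = %s%s\n",
              x$family, x$loglik, x$converged,
              if (x$singular) ", singular" else ""))
  tab <- data.frame(estimate = x$estimates, se = x$standard_errors)
  print(round(tab, 4))
  if (length(x$non_estimable)) {
    cat("non-estimable terms:", paste(x$non_estimable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wald z-test of a fixed effect against a reference value
#'
#' The statistic is the difference between the estimate and the reference
#' value in units of the estimate's standard error; the p-value is the
#' two-tailed standard-normal tail probability. This is how an intercept is
#' compared with a chance level expressed in link space (e.g. `logit(1/6)`
#' for guessing one object out of six).
#'
#' @param fit a `uds_fit`.
#' @param term name of the fixed term (e.g. `"(Intercept)"`).
#' @param reference_value null value on the link scale (default 0).
#' @return a `uds_test` with `statistic`, `df = NA`, `p_value`,
#'   `method = "wald-z"`.
#' @export
wald_test <- function(fit, term = "(Intercept)", reference_value = 0) {
  stopifnot(inherits(fit, "uds_fit"))
  if (!term %in% names(fit$estimates) || term %in% fit$non_estimable) {
    stop(sprintf("term '%s' is not estimable in this fit", term), call. = FALSE)
  }
  z <- (fit$estimates[[term]] - reference_value) / fit$standard_errors[[term]]
  structure(list(statistic = as.numeric(z), df = NA_integer_,
                 p_value = 2 * stats::pnorm(-abs(z)), method = "wald-z",
                 term = term, reference_value = reference_value),
            class = "uds_test")
}

#' Likelihood-ratio test of nested fits
#'
#' Twice the log-likelihood difference, referred to a chi-square distribution
#' with degrees of freedom equal to the difference in number of fixed-effect
#' terms. Both fits must use the same rows; the reduced model must be nested
#' in the full one.
#'
#' @param fit_full,fit_reduced `uds_fit` objects.
#' @return a `uds_test` with `method = "lrt"`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "uds_fit"), inherits(fit_reduced, "uds_fit"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("full and reduced fits use different numbers of rows", call. = FALSE)
  }
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6) {
    stop(sprintf(paste("full-model log-likelihood (%.6f) is below the reduced model's",
                       "(%.6f): optimizer failure, refit before testing"),
                 fit_full$loglik, fit_reduced$loglik), call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- length(fit_full$estimates) - length(fit_reduced$estimates)
  if (df == 0L && stat < 1e-8) {
    # degenerate comparison of identical models
    return(structure(list(statistic = 0, df = 0L, p_value = 1, method = "lrt"),
                     class = "uds_test"))
  }
  if (df < 1L) stop("reduced model is not nested in the full model", call. = FALSE)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "lrt"),
            class = "uds_test")
}

#' @export
print.uds_test <- function(x, ...) {
  cat(sprintf("<uds_test> %s: statistic = %.4f%s, p = %.4g\n", x$method,
              x$statistic, if (!is.na(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Parametric bootstrap percentile confidence intervals
#'
#' Simulates `n_boot` response sets from the fitted model, refits each, and
#' returns percentile intervals for all fixed-effect estimates and,
#' optionally, for population-level fitted probabilities at supplied
#' predictor settings. Non-convergent or failed refits are discarded and
#' counted; more than 20% failures aborts with an error rather than quietly
#' narrowing the intervals.
#'
#' @param fit a converged `uds_fit` (mixed, plain-glm, or beta).
#' @param n_boot number of bootstrap data sets (the headline analyses use
#'   1000; simulation studies may use fewer).
#' @param level interval level, default 0.95.
#' @param seed integer seed; identical seeds give identical intervals.
#' @param fitted_newdata optional data.frame of predictor settings at which
#'   population-level fitted probabilities (random effects at 0) are also
#'   bootstrapped.
#' @return a `uds_intervals` object: matrix `estimates` (rows = terms,
#'   columns lower/upper), optional matrix `fitted`, plus `n_boot`,
#'   `n_failed`, `level`.
#' @export
parametric_bootstrap_ci <- function(fit, n_boot = 1000, level = 0.95, seed,
                                    fitted_newdata = NULL) {
  stopifnot(inherits(fit, "uds_fit"))
  if (!fit$converged) stop("parametric bootstrap requires a converged fit", call. = FALSE)
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, "bootstrap"))

  terms <- names(fit$estimates)
  draws <- matrix(NA_real_, n_boot, length(terms), dimnames = list(NULL, terms))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    bfit <- try(refit_simulated(fit), silent = TRUE)
    if (inherits(bfit, "try-error") || is.null(bfit)) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- bfit[terms]
    }
  }
  if (n_failed > 0.2 * n_boot) {
    stop(sprintf("parametric bootstrap: %d of %d refits failed (> 20%%)",
                 n_failed, n_boot), call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ok <- stats::complete.cases(draws)
  est_ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = probs))
  colnames(est_ci) <- c("lower", "upper")

  fitted_ci <- NULL
  if (!is.null(fitted_newdata)) {
    X <- stats::model.matrix(
      stats::reformulate(if (length(fit$spec$fixed_terms)) fit$spec$fixed_terms else "1"),
      fitted_newdata)
    fdraws <- inv_logit(draws[ok, colnames(X), drop = FALSE] %*% t(X))
    fitted_ci <- t(apply(fdraws, 2, stats::quantile, probs = probs))
    colnames(fitted_ci) <- c("lower", "upper")
  }
  structure(list(estimates = est_ci, fitted = fitted_ci,
                 n_boot = n_boot, n_failed = n_failed, level = level),
            class = "uds_intervals")
}

# Simulate one response set from `fit`, refit, return named fixed-effect
# vector (or NULL / error on failure).
refit_simulated <- function(fit) {
  if (inherits(fit$model, "merMod")) {
    newresp <- stats::simulate(fit$model)[[1]]
    rf <- suppressMessages(suppressWarnings(lme4::refit(fit$model, newresp = newresp)))
    conv_msgs <- rf@optinfo$conv$lme4$messages %||% character()
    if (rf@optinfo$conv$opt != 0 ||
        any(grepl("failed to converge", conv_msgs, ignore.case = TRUE))) {
      return(NULL)
    }
    lme4::fixef(rf)
  } else if (inherits(fit$model, "glm")) {
    newresp <- stats::simulate(fit$model)[[1]]
    dat <- fit$model$data
    form <- stats::formula(fit$model)
    if (is.matrix(newresp)) {
      dat[[fit$spec$response[1]]] <- newresp[, 1]
      dat[[fit$spec$response[2]]] <- newresp[, 2]
    } else {
      dat[[fit$spec$response[1]]] <- newresp
    }
    rf <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
    if (!rf$converged) return(NULL)
    stats::coef(rf)
  } else if (identical(fit$family, "beta")) {
    mu <- inv_logit(as.numeric(fit$X %*% fit$estimates[colnames(fit$X)]))
    phi <- fit$precision
    y <- stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
    # beta draws can hit the boundary in floating point; nudge inside
    y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    dat <- fit$data
    dat[[fit$spec$response]] <- y
    rf <- fit_beta_glm(dat, fit$spec$response, fit$spec$fixed_terms)
    if (!rf$converged) return(NULL)
    rf$estimates
  } else {
    stop("unsupported fit type for parametric bootstrap", call. = FALSE)
  }
}

#' @export
print.uds_intervals <- function(x, ...) {
  cat(sprintf("<uds_intervals> %g%% parametric bootstrap, n_boot = %d (failed: %d)\n",
              100 * x$level, x$n_boot, x$n_failed))
  print(round(x$estimates, 4))
  invisible(x)
}
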