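#' Beta regression with logit link
#'
#' Maximum-likelihood fit of a beta error model for responses strictly inside
#' (0, 1): the mean follows a logit-linear predictor and a single scalar
#' precision parameter phi is estimated jointly, with
#' `y ~ Beta(mu * phi, (1 - mu) * phi)`. Standard errors come from the
#' observed information (numerical Hessian at the optimum). Used for the
#' chance-corrected sampling statistic, whose chance reference is 0.5 on the
#' probability scale, i.e. 0 in link space since `logit(0.5) = 0`.
#'
#' @param table data.frame with the response and any predictors.
#' @param response_column name of the response column; all values must lie
#'   strictly inside (0, 1). Boundary values are an upstream exclusion
#'   problem, not something this fitter smooths over.
#' @param fixed_terms character vector of predictor columns; empty for an
#'   intercept-only model.
#' @return a `uds_fit` with `family = "beta"`; `varcomps` holds the
#'   precision estimate.
#' @export
fit_beta_glm <- function(table, response_column, fixed_terms = character()) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  if (!response_column %in% names(table)) {
    stop(sprintf("column '%s' not found in table", response_column), call. = FALSE)
  }
  y <- table[[response_column]]
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    stop("beta regression needs responses strictly inside (0, 1); ",
         "exclude boundary cases upstream", call. = FALSE)
  }
  X <- stats::model.matrix(
    stats::reformulate(if (length(fixed_terms)) fixed_terms else "1"), table)

  negll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    phi <- exp(par[length(par)])
    mu <- inv_logit(as.numeric(X %*% beta))
    ll <- stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }

  # moment-based starting values
  start_beta <- stats::coef(stats::lm.fit(X, logit(pmin(pmax(y, 1e-6), 1 - 1e-6))))
  v <- stats::var(y)
  mbar <- mean(y)
  start_phi <- log(max(mbar * (1 - mbar) / max(v, 1e-6) - 1, 1))
  opt <- stats::optim(c(start_beta, start_phi), negll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))

  np <- ncol(X)
  est <- stats::setNames(opt$par[seq_len(np)], colnames(X))
  se <- rep(NA_real_, np)
  ok <- TRUE
  h <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(h, "try-error") && all(diag(h)[seq_len(np)] > 0)) {
    se <- sqrt(diag(h)[seq_len(np)])
  } else {
    ok <- FALSE
  }
  structure(list(
    estimates = est,
    standard_errors = stats::setNames(se, colnames(X)),
    varcomps = list(precision = exp(opt$par[np + 1L])),
    precision = exp(opt$par[np + 1L]),
    loglik = -opt$value,
    converged = opt$convergence == 0 && ok,
    singular = FALSE,
    non_estimable = character(),
    n_obs = length(y),
    n_groups = integer(),
    family = "beta",
    spec = model_spec(response_column, fixed_terms, family = "beta"),
    X = X,
    data = table,
    model = NULL
  ), class = "uds_fit")
}
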