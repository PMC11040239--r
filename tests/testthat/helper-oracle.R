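# Independent quadrature oracle for single-factor logistic mixed models.
# Deliberately shares no code with the package's fitting path (which
# delegates to lme4): Gauss-Hermite nodes come from the Golub-Welsch
# eigendecomposition and the marginal likelihood is integrated directly.

gh_nodes <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Marginal log-likelihood of successes/totals ~ logit(b0 + b1*x + u_g),
# u_g ~ N(0, sigma^2), by n_nodes-point Gauss-Hermite quadrature.
oracle_loglik <- function(par, successes, totals, x, g, n_nodes = 40) {
  q <- gh_nodes(n_nodes)
  b0 <- par[1]; b1 <- par[2]; sigma <- exp(par[3])
  ll <- 0
  for (k in unique(g)) {
    ix <- g == k
    f <- vapply(q$x, function(z) {
      p <- stats::plogis(b0 + b1 * x[ix] + sigma * sqrt(2) * z)
      prod(stats::dbinom(successes[ix], totals[ix], p))
    }, 0)
    ll <- ll + log(sum(q$w * f) / sqrt(pi))
  }
  ll
}

# Brute-force ML fit under the quadrature likelihood; returns the deviance
# (includes the binomial normalizing constants, matching lme4's deviance).
oracle_fit_deviance <- function(successes, totals, x, g, n_nodes = 40) {
  nll <- function(p) -oracle_loglik(p, successes, totals, x, g, n_nodes)
  # multi-start over the variance scale so the brute-force optimum is trusted
  start_beta <- stats::coef(stats::glm(cbind(successes, totals - successes) ~ x,
                                       family = stats::binomial()))
  best <- NULL
  for (ls in log(c(0.1, 0.5, 1, 2))) {
    opt <- stats::optim(c(start_beta, ls), nll, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(deviance = 2 * best$value, par = best$par)
}

# One tiny single-factor instance (spec of the toy: n_groups clusters of
# cluster_size rows, one continuous predictor, binary or binomial(3) rows).
make_toy_instance <- function(seed, n_groups = 6, cluster_size = 4,
                              trials = 1L, sigma = 0.8) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = cluster_size)
  x <- stats::rnorm(n_groups * cluster_size)
  u <- stats::rnorm(n_groups, 0, sigma)
  p <- stats::plogis(-0.3 + 0.5 * x + u[g])
  s <- stats::rbinom(length(p), trials, p)
  data.frame(successes = s, failures = trials - s, tot = trials,
             x = x, grp = factor(g))
}
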