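# Independent maximum-likelihood oracle for the logit fit: direct BFGS
# optimisation of the Bernoulli log-likelihood with analytic gradient —
# no IRLS involved, so it is a genuinely separate route to the estimates.
logit_mle_oracle <- function(records) {
  X <- cbind(1, records$occupancy)
  y <- records$fp
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) as.numeric(t(X) %*% (stats::plogis(X %*% b) - y))
  stats::optim(c(0, 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}

# Bernoulli outcomes with logit-linear dependence on a uniform covariate.
sim_records <- function(n, a, b, seed) {
  set.seed(seed)
  occ <- stats::runif(n)
  data.frame(fp = stats::rbinom(n, 1, stats::plogis(a + b * occ)),
             occupancy = occ)
}
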