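# Internal sampler for the hierarchical Hill dose-response model.
#
# Likelihood: y_ij ~ TruncNormal(mu_ij, sigma; 0, U) with
#   mu_ij = 100 / (1 + (c_i / Kd_j)^{h_j}).
# Parameters per curve j: theta_j = log10 Kd_j (uniform prior on a fixed
# interval) and eta_j = log h_j, partially pooled within compounds:
#   eta_j ~ N(m_{compound(j)}, s_w),  m_c ~ N(hill_prior_mu, s_b),
# with s_w = s_b = hill_prior_sd / sqrt(2) so the marginal sd of eta is
# hill_prior_sd. A single observation sd sigma is pooled globally with a
# half-normal prior.
#
# The sampler is a random-walk-Metropolis-within-Gibbs sweep vectorised
# across curves: all (theta_j, eta_j) pairs are proposed and accepted
# jointly per iteration; compound means are conjugate normal draws; log
# sigma gets a scalar random-walk step. Step sizes adapt per curve during
# warmup toward ~30% acceptance.

# log-density of the truncated-normal observation model, summed per curve
.curve_loglik <- function(y, logc, curve, theta, eta, sigma, upper) {
  mu <- 100 / (1 + exp(exp(eta[curve]) * (logc - log(10) * theta[curve])))
  ll <- stats::dnorm(y, mu, sigma, log = TRUE) -
    log(stats::pnorm(upper, mu, sigma) - stats::pnorm(0, mu, sigma))
  rowsum(ll, curve, reorder = TRUE)[, 1]
}

.run_chain <- function(dat, config, chain_seed) {
  set.seed(chain_seed)
  y <- dat$y
  logc <- dat$logc
  curve <- dat$curve
  comp <- dat$comp # compound index per curve
  n_curve <- dat$n_curve
  n_comp <- dat$n_comp

  lo <- config$log10_kd_prior[1]
  hi <- config$log10_kd_prior[2]
  mu0 <- config$hill_prior_mu
  s_w <- config$hill_prior_sd / sqrt(2)
  s_b <- config$hill_prior_sd / sqrt(2)
  obs_scale <- config$obs_sd_prior
  upper <- config$upper_clip

  n_warm <- config$n_warmup
  n_draw <- config$n_draws

  theta <- stats::runif(n_curve, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
  eta <- stats::rnorm(n_curve, mu0, 0.05)
  m <- rep(mu0, n_comp)
  sigma <- stats::runif(1, 3, 10)

  step <- rep(0.6, n_curve)
  step_s <- 0.3
  acc_n <- rep(0L, n_curve)
  acc_s <- 0L

  cur_ll <- .curve_loglik(y, logc, curve, theta, eta, sigma, upper)

  th_draws <- matrix(NA_real_, n_draw, n_curve)
  et_draws <- matrix(NA_real_, n_draw, n_curve)
  sig_draws <- numeric(n_draw)

  n_curve_per_comp <- tabulate(comp, nbins = n_comp)

  for (it in seq_len(n_warm + n_draw)) {
    # (a) joint per-curve random-walk update of (theta, eta)
    th2 <- theta + stats::rnorm(n_curve) * step
    et2 <- eta + stats::rnorm(n_curve) * step * 0.5
    inside <- th2 >= lo & th2 <= hi
    ll2 <- .curve_loglik(y, logc, curve, th2, et2, sigma, upper)
    logr <- (ll2 - cur_ll) +
      stats::dnorm(et2, m[comp], s_w, log = TRUE) -
      stats::dnorm(eta, m[comp], s_w, log = TRUE)
    acc <- inside & log(stats::runif(n_curve)) < logr
    theta[acc] <- th2[acc]
    eta[acc] <- et2[acc]
    cur_ll[acc] <- ll2[acc]
    acc_n <- acc_n + acc

    # (b) conjugate update of compound-level Hill means
    sum_eta <- rowsum(eta, comp, reorder = TRUE)[, 1]
    prec <- 1 / s_b^2 + n_curve_per_comp / s_w^2
    mean_post <- (mu0 / s_b^2 + sum_eta / s_w^2) / prec
    m <- stats::rnorm(n_comp, mean_post, 1 / sqrt(prec))

    # (c) scalar update of log sigma (half-normal prior, log-scale Jacobian)
    ls2 <- log(sigma) + stats::rnorm(1) * step_s
    sig2 <- exp(ls2)
    ll_new <- .curve_loglik(y, logc, curve, theta, eta, sig2, upper)
    logr_s <- (sum(ll_new) - sum(cur_ll)) +
      (-sig2^2 + sigma^2) / (2 * obs_scale^2) + (ls2 - log(sigma))
    if (log(stats::runif(1)) < logr_s) {
      sigma <- sig2
      cur_ll <- ll_new
      acc_s <- acc_s + 1L
    }

    # step-size adaptation during warmup
    if (it <= n_warm && it %% 25 == 0) {
      rate <- acc_n / 25
      step <- step * exp(pmin(pmax(rate - 0.3, -0.25), 0.25))
      acc_n <- rep(0L, n_curve)
      rate_s <- acc_s / 25
      step_s <- step_s * exp(pmin(pmax(rate_s - 0.3, -0.25), 0.25))
      acc_s <- 0L
    }

    if (it > n_warm) {
      j <- it - n_warm
      th_draws[j, ] <- theta
      et_draws[j, ] <- eta
      sig_draws[j] <- sigma
    }
  }
  list(theta = th_draws, eta = et_draws, sigma = sig_draws)
}

# MAP + Laplace approximation, one curve at a time. Hill prior uses the
# marginal (unpooled) sd; sigma is profiled per curve with the same
# half-normal prior. Returns median/CI columns compatible with the MCMC
# summaries (rhat/ess are NA in this mode).
.fit_map_curve <- function(y, logc, config) {
  lo <- config$log10_kd_prior[1]
  hi <- config$log10_kd_prior[2]
  mu0 <- config$hill_prior_mu
  s_h <- config$hill_prior_sd
  obs_scale <- config$obs_sd_prior
  upper <- config$upper_clip

  negpost <- function(par) {
    theta <- par[1]; eta <- par[2]; sigma <- exp(par[3])
    mu <- 100 / (1 + exp(exp(eta) * (logc - log(10) * theta)))
    ll <- sum(stats::dnorm(y, mu, sigma, log = TRUE) -
                log(stats::pnorm(upper, mu, sigma) - stats::pnorm(0, mu, sigma)))
    lp <- stats::dnorm(eta, mu0, s_h, log = TRUE) -
      sigma^2 / (2 * obs_scale^2) + par[3]
    -(ll + lp)
  }
  # coarse grid initialisation over theta avoids the flat-likelihood plateau
  grid <- seq(lo + 0.05, hi - 0.05, length.out = 29)
  v <- vapply(grid, function(g) negpost(c(g, mu0, log(5))), numeric(1))
  init <- c(grid[which.min(v)], mu0, log(5))
  opt <- stats::optim(init, negpost, method = "L-BFGS-B",
                      lower = c(lo, mu0 - 5 * s_h, log(0.5)),
                      upper = c(hi, mu0 + 5 * s_h, log(60)),
                      hessian = TRUE)
  se <- tryCatch({
    v <- solve(opt$hessian)[1, 1]
    if (is.finite(v) && v > 0) sqrt(v) else Inf
  }, error = function(e) Inf)
  se <- min(se, (hi - lo) / 2)
  list(theta = opt$par[1],
       theta_lo = max(lo, opt$par[1] - 1.96 * se),
       theta_hi = min(hi, opt$par[1] + 1.96 * se),
       hill = exp(opt$par[2]))
}
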