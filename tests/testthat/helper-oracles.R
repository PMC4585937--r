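# Shared generative truths and independent oracles for the test suite.
# The oracles simulate the observer's generative process directly (or search
# the likelihood by brute force) and never call the closed forms under test.

# the calibrated reference observer: prior variance solved from the
# proprioceptive-only probit slope 0.02 at likelihood variance 34
calibrated_params <- function(...) {
  observer_params(sigma2_prop = 34, sigma2_tact = 11,
                  sigma2_prior_prop = calibrate_prior_variance(0.02, 34),
                  v_pursuit = 10.8, ...)
}

# independent two-stage sampler: noisy measurement per channel, then a draw
# from its conjugate-Gaussian posterior, then the sum
sample_fused_oracle <- function(params, n, v_surf, v_prop,
                                active = TRUE, low = FALSE) {
  s2t <- params$sigma2_tact * if (low) params$kappa_low_amp else 1
  wt <- params$sigma2_prior_tact / (params$sigma2_prior_tact + s2t)
  tau2t <- wt * s2t
  m_t <- rnorm(n, mean = if (active) v_surf - v_prop else v_surf,
               sd = sqrt(s2t))
  d_t <- rnorm(n, mean = wt * m_t, sd = sqrt(tau2t))
  if (!active) {
    return(d_t)
  }
  s2p <- params$sigma2_prop
  wp <- params$sigma2_prior_prop / (params$sigma2_prior_prop + s2p)
  tau2p <- wp * s2p
  m_p <- rnorm(n, mean = v_prop, sd = sqrt(s2p))
  d_p <- rnorm(n, mean = wp * m_p, sd = sqrt(tau2p))
  d_p + d_t
}

# random but well-behaved observer parameter sets for property loops
random_observer_params <- function() {
  observer_params(sigma2_prop = runif(1, 2, 120),
                  sigma2_tact = runif(1, 2, 60),
                  sigma2_prior_prop = runif(1, 0.1, 5),
                  sigma2_prior_tact = runif(1, 0.1, 5),
                  v_pursuit = runif(1, 4, 18),
                  kappa_low_amp = runif(1, 1, 3))
}

# brute-force zooming grid search over the Bernoulli/binomial probit
# likelihood; independent of glm
grid_probit_oracle <- function(trials, b0_span = c(-3, 3),
                               b1_span = c(-0.5, 0.5), n_iter = 6L,
                               n_grid = 61L) {
  agg <- stats::aggregate(response ~ v_surf, trials, function(y) {
    c(k = sum(y), n = length(y))
  })
  v <- agg$v_surf
  k <- agg$response[, "k"]
  n <- agg$response[, "n"]
  ll <- function(b0, b1) {
    p <- pmin(pmax(pnorm(b0 + b1 * v), 1e-12), 1 - 1e-12)
    sum(k * log(p) + (n - k) * log(1 - p))
  }
  for (iter in seq_len(n_iter)) {
    g0 <- seq(b0_span[1], b0_span[2], length.out = n_grid)
    g1 <- seq(b1_span[1], b1_span[2], length.out = n_grid)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    step0 <- diff(g0[1:2])
    step1 <- diff(g1[1:2])
    b0_span <- g0[best[1]] + c(-2, 2) * step0
    b1_span <- g1[best[2]] + c(-2, 2) * step1
  }
  c(intercept = g0[best[1]], slope = g1[best[2]])
}
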