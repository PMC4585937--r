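test_that("shrinkage weight follows the conjugate-Gaussian update", {
  ch <- shrinkage_weight(1, 1)
  expect_equal(ch$weight, 0.5)
  expect_equal(ch$post_var, 0.5)

  # noiseless likelihood dominates the prior
  ch0 <- shrinkage_weight(1, 1e-12)
  expect_gt(ch0$weight, 1 - 1e-10)
  expect_lt(ch0$post_var, 1e-10)

  # strictly decreasing in the likelihood variance; posterior tighter than it
  s2 <- c(0.5, 1, 5, 50, 500)
  w <- shrinkage_weight(1, s2)$weight
  expect_true(all(diff(w) < 0))
  expect_true(all(shrinkage_weight(1, s2)$post_var < s2))

  expect_error(shrinkage_weight(0, 1), "positive")
  expect_error(shrinkage_weight(1, -2), "positive")
})

test_that("shrinkage weight equals the Monte-Carlo posterior-mean coefficient", {
  # joint-Gaussian oracle: with v ~ N(0, s2_prior) and m | v ~ N(v, s2_like),
  # E[v | m] = (cov(v, m) / var(m)) * m; the regression coefficient of v on m
  # estimated from simulation must match the closed-form weight
  set.seed(41)
  for (pars in list(c(1, 1), c(0.4754, 34), c(2, 0.5))) {
    n <- 1e6
    v <- rnorm(n, 0, sqrt(pars[1]))
    m <- rnorm(n, v, sqrt(pars[2]))
    fit <- lm(v ~ 0 + m)
    w_hat <- coef(fit)[[1]]
    se <- summary(fit)$coefficients[1, 2]
    expect_lt(abs(w_hat - shrinkage_weight(pars[1], pars[2])$weight), 3 * se)
  }
})

test_that("fused estimate matches the two-stage sampling process", {
  # equal weights cancel: stationary surface perceived as unbiased
  p_eq <- observer_params(sigma2_prop = 10, sigma2_tact = 10,
                          sigma2_prior_prop = 1)
  expect_equal(fused_distribution(p_eq, 0, v_prop = 10)$mean, 0)
  # without proprioception the mean is proportional to v_surf
  expect_equal(fused_distribution(p_eq, 0, proprioception_active = FALSE)$mean, 0)

  # the illusion: stationary surface during pursuit is perceived moving
  # toward the body (negative)
  fe <- fused_distribution(calibrated_params(), 0, v_prop = 10.8)
  expect_lt(fe$mean, 0)

  # closed-form mean and sd match 1e6 two-stage samples within 3 SE
  set.seed(42)
  cases <- list(list(p = calibrated_params(), v_surf = 0, v_prop = 10.8,
                     active = TRUE),
                list(p = random_observer_params(), v_surf = 12, v_prop = 8,
                     active = TRUE),
                list(p = random_observer_params(), v_surf = -5, v_prop = 0,
                     active = FALSE))
  for (cs in cases) {
    draws <- sample_fused_oracle(cs$p, 1e6, cs$v_surf, cs$v_prop, cs$active)
    fe <- fused_distribution(cs$p, cs$v_surf, cs$v_prop, cs$active)
    expect_lt(abs(mean(draws) - fe$mean), 3 * sd(draws) / sqrt(1e6))
    expect_lt(abs(sd(draws) - fe$sd), 3 * fe$sd / sqrt(2 * 1e6))
  }

  # a pursuit geometry with zero finger velocity is the control formulation
  pp <- calibrated_params()
  expect_equal(fused_distribution(pp, 5, v_prop = 0)$mean,
               fused_distribution(pp, 5, proprioception_active = FALSE)$mean)
})

test_that("response probability is the away-probability of the fused estimate", {
  pp <- calibrated_params()
  pse <- predicted_psychometric(pp, "main")$pse
  expect_equal(response_probability(pp, pse), 0.5, tolerance = 1e-10)
  expect_gt(response_probability(pp, 1e4), 1 - 1e-8)

  # strictly increasing in v_surf
  v <- seq(-40, 40, by = 5)
  expect_true(all(diff(response_probability(pp, v)) > 0))

  # matches the empirical away-fraction of simulated two-stage responses
  set.seed(43)
  for (i in 1:5) {
    pars <- random_observer_params()
    v_surf <- runif(1, -15, 15)
    draws <- sample_fused_oracle(pars, 1e5, v_surf, pars$v_pursuit)
    p_hat <- mean(draws > 0)
    p <- response_probability(pars, v_surf)
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(p_hat - p), 3 * se + 1e-5)
  }
})

test_that("predicted psychometric carries the structure of the illusion", {
  # control task is structurally unbiased for any parameters
  set.seed(44)
  for (i in 1:25) {
    expect_identical(predicted_psychometric(random_observer_params(),
                                            "control")$pse, 0)
  }

  # no noise asymmetry (single prior), no illusion
  p_eq <- observer_params(sigma2_prop = 7, sigma2_tact = 7,
                          sigma2_prior_prop = 0.8)
  expect_equal(predicted_psychometric(p_eq, "main")$pse, 0)

  # PSE grows with proprioceptive noise and shrinks as tactile noise rises
  pse_at <- function(s2p, s2t) {
    predicted_psychometric(observer_params(sigma2_prop = s2p,
                                           sigma2_tact = s2t,
                                           sigma2_prior_prop = 0.5),
                           "main")$pse
  }
  expect_true(all(diff(sapply(c(10, 20, 40, 80), pse_at, s2t = 5)) > 0))
  expect_true(all(diff(sapply(c(2, 4, 8, 16), function(s2t) {
    pse_at(s2p = 34, s2t)
  })) < 0))

  # the low-amplitude condition reduces the predicted bias
  pp <- calibrated_params(kappa_low_amp = 2)
  expect_lt(predicted_psychometric(pp, "main", low_amplitude = TRUE)$pse,
            predicted_psychometric(pp, "main", low_amplitude = FALSE)$pse)

  # intercept/slope/pse are mutually consistent
  pm <- predicted_psychometric(pp, "main")
  expect_equal(-pm$intercept / pm$slope, pm$pse, tolerance = 1e-12)
})

test_that("unimodal slope matches a probit refit of simulated judgements", {
  set.seed(45)
  for (pars in list(c(0.4754, 34), c(0.4754, 11), c(2, 20))) {
    v <- rep(seq(-40, 40, by = 10), each = 1.25e4)
    dummy <- observer_params(sigma2_prop = 1, sigma2_tact = pars[2],
                             sigma2_prior_prop = 1,
                             sigma2_prior_tact = pars[1])
    perceived <- sample_fused_oracle(dummy, length(v), v, 0, active = FALSE)
    fit <- suppressWarnings(
      glm((perceived > 0) ~ v, family = binomial("probit")))
    slope_hat <- coef(fit)[2]
    se <- sqrt(vcov(fit)[2, 2])
    expect_lt(abs(slope_hat - predicted_unimodal_slope(pars[1], pars[2])),
              2 * se)
  }
})

test_that("prior calibration inverts the predicted unimodal slope", {
  for (s2 in c(5, 11, 34, 80)) {
    upper <- 1 / sqrt(2 * s2)
    for (target in upper * c(0.1, 0.5, 0.9)) {
      s2_prior <- calibrate_prior_variance(target, s2)
      expect_equal(predicted_unimodal_slope(s2_prior, s2), target,
                   tolerance = 1e-10)
    }
    expect_error(calibrate_prior_variance(upper, s2), "slope_target")
    expect_error(calibrate_prior_variance(0, s2), "slope_target")
  }
})

test_that("JND conversion, Filehne gain and biased summation behave as defined", {
  expect_equal(jnd_from_slope(qnorm(0.75)), 1)
  expect_error(jnd_from_slope(0), "slope")
  expect_error(jnd_from_slope(-1), "slope")

  expect_equal(filehne_gain(6.8, 10.8), 1 - 6.8 / 10.8)
  expect_equal(filehne_gain(0, 7), 1)    # unbiased observer: full compensation
  expect_equal(filehne_gain(10.8, 10.8), 0)  # PSE at hand speed: none
  expect_error(filehne_gain(5, 0), "nonzero")

  # gain 1 recovers ideal velocity summation
  expect_equal(perceived_velocity_biased(-3, 10, 1), 7)
  # stationary surface with an incomplete gain appears to move opposite
  # the hand: v_prop * (gain - 1)
  expect_equal(perceived_velocity_biased(-10.8, 10.8, 0.6), -4.32)
  expect_lt(perceived_velocity_biased(-10.8, 10.8, 0.37), 0)
})

test_that("weights and PSE are scale-invariant; slopes scale as 1/sqrt(c)", {
  base <- calibrated_params()
  for (c_scale in c(0.25, 4, 9)) {
    scaled <- observer_params(
      sigma2_prop = base$sigma2_prop * c_scale,
      sigma2_tact = base$sigma2_tact * c_scale,
      sigma2_prior_prop = base$sigma2_prior_prop * c_scale,
      v_pursuit = base$v_pursuit)
    p0 <- predicted_psychometric(base, "main")
    p1 <- predicted_psychometric(scaled, "main")
    expect_equal(p1$pse, p0$pse, tolerance = 1e-12)
    expect_equal(p1$slope, p0$slope / sqrt(c_scale), tolerance = 1e-12)
    f0 <- fused_distribution(base, 3)
    f1 <- fused_distribution(scaled, 3)
    expect_equal(f1$w_prop, f0$w_prop, tolerance = 1e-12)
    expect_equal(f1$w_tact, f0$w_tact, tolerance = 1e-12)
  }
})
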