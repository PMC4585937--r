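# simulate one observer-condition from a known probit function
sim_probit_trials <- function(b0, b1, velocities, reps, seed) {
  set.seed(seed)
  d <- data.frame(v_surf = rep(velocities, each = reps))
  d$response <- rbinom(nrow(d), 1, pnorm(b0 + b1 * d$v_surf))
  d
}

test_that("probit ML fit matches the grid-search likelihood oracle", {
  trials <- sim_probit_trials(-0.3, 0.045, seq(-30, 30, 10), 40, seed = 21)
  fit <- fit_probit_ml(trials)
  oracle <- grid_probit_oracle(trials)
  expect_lt(abs(fit$coefficients["intercept"] - oracle["intercept"]), 1e-4)
  expect_lt(abs(fit$coefficients["slope"] - oracle["slope"]), 1e-4)
  # ML property: fitted likelihood at least as high as at the truth
  ll_at <- function(b0, b1) {
    p <- pnorm(b0 + b1 * trials$v_surf)
    sum(trials$response * log(p) + (1 - trials$response) * log(1 - p))
  }
  expect_gte(fit$loglik, ll_at(-0.3, 0.045))
})

test_that("per-observer recovery matches the representative-observer regime", {
  # generative truths in the range of the two printed example observers:
  # control PSE -1.5 (slope 0.06), main PSE 11.5 (slope 0.0425)
  ctrl <- sim_probit_trials(1.5 * 0.06, 0.06,
                            setdiff(seq(-30, 30, 10), 0), 15, seed = 22)
  fit_c <- fit_probit_ml(ctrl)
  expect_lt(abs(fit_c$pse - (-1.5)), 2 * fit_c$pse_se)

  main <- sim_probit_trials(-11.5 * 0.0425, 0.0425, seq(-30, 30, 10), 15,
                            seed = 23)
  fit_m <- fit_probit_ml(main)
  expect_lt(abs(fit_m$pse - 11.5), 2 * fit_m$pse_se)
  expect_true(is.finite(fit_m$jnd) && fit_m$jnd > 0)
})

test_that("degenerate response patterns are flagged, not silently fitted", {
  # complete separation: a perfect step function
  step <- data.frame(v_surf = rep(c(-20, -10, 10, 20), each = 10))
  step$response <- as.integer(step$v_surf > 0)
  fit <- fit_probit_ml(step)
  expect_true(fit$flags$separation)
  expect_true(is.na(fit$pse))

  # chance-level flat responding: slope ~ 0, PSE undefined
  flat <- data.frame(v_surf = rep(c(-20, -10, 10, 20), each = 10),
                     response = rep_len(c(0L, 1L), 40))
  fitf <- fit_probit_ml(flat)
  expect_true(fitf$flags$flat_slope)
  expect_true(is.na(fitf$pse))

  # constant responses are an exclusion-grade error
  const <- data.frame(v_surf = rep(c(-10, 10), each = 5),
                      response = rep(1L, 10))
  expect_error(fit_probit_ml(const), "constant response")
  expect_error(fit_probit_ml(data.frame(v_surf = rep(1, 10),
                                        response = rep_len(0:1, 10))),
               "distinct velocity")
})

test_that("hierarchical fit collapses to the pooled fit without heterogeneity", {
  d <- make_design("exp1")
  spec0 <- population_spec(6, re_covariance = matrix(0, 2, 2))
  tr <- simulate_population(spec0, d, seed = 24)
  hier <- fit_hierarchical_probit(tr)
  pooled_m <- fit_probit_ml(tr[tr$condition == "main", ])
  fx <- hier$fixed
  expect_lt(abs(fx$slope[fx$condition == "main"] -
                  pooled_m$coefficients["slope"]),
            2 * sqrt(pooled_m$vcov[2, 2]) + 1e-3)
  expect_lt(abs(fx$pse[fx$condition == "main"] - pooled_m$pse),
            2 * pooled_m$pse_se + 0.1)
})

test_that("hierarchical fit recovers the group-level generative truth", {
  d <- make_design("exp1")
  spec <- population_spec(10)  # PSEs 6.8 (main) and -1.6 (control)
  tr <- simulate_population(spec, d, seed = 25)
  hier <- fit_hierarchical_probit(tr)
  fx <- hier$fixed
  expect_lt(abs(fx$pse[fx$condition == "main"] - 6.8),
            3 * fx$pse_se[fx$condition == "main"])
  expect_lt(abs(fx$pse[fx$condition == "control"] - (-1.6)),
            3 * fx$pse_se[fx$condition == "control"])
  # the random-effect covariance is PSD with both variances represented
  ev <- eigen(hier$re_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))

  # invariance to observer relabelling and trial order
  tr_perm <- tr[sample.int(nrow(tr)), ]
  tr_perm$observer_id <- factor(tr_perm$observer_id,
                                labels = sample(LETTERS[1:10]))
  hier2 <- fit_hierarchical_probit(tr_perm)
  expect_equal(hier2$fixed$pse, fx$pse, tolerance = 1e-6)
})

test_that("hierarchical parametric bootstrap brackets the PSEs", {
  d <- make_design("exp1", reps_main = 8, reps_control = 8)
  spec <- population_spec(5)
  tr <- simulate_population(spec, d, seed = 26)
  hier <- fit_hierarchical_probit(tr)
  boot <- bootstrap_pse_ci(hier, n_reps = 40, seed = 27)
  expect_lte(boot$n_failed, 8)
  expect_true(all(c("main", "control") %in% names(boot$replicates)))
  # percentile bounds bracket the central mass of the replicates
  ci_main <- boot$ci[boot$ci$quantity == "main", ]
  expect_gte(mean(boot$replicates$main >= ci_main$lower &
                    boot$replicates$main <= ci_main$upper), 0.9)
  # the difference column subtracts the second condition from the first
  expect_equal(boot$replicates[[3]],
               boot$replicates[[1]] - boot$replicates[[2]])
  dci <- pse_difference_ci(boot, "main", "control")
  expect_equal(dci$estimate,
               unname(boot$point["main"] - boot$point["control"]))
  expect_true(is.logical(dci$excludes_zero))
})

test_that("single-fit parametric bootstrap is exact in the degenerate case", {
  trials <- sim_probit_trials(-0.2, 0.05, seq(-30, 30, 10), 20, seed = 28)
  fit <- fit_probit_ml(trials)
  b1 <- bootstrap_pse_ci(fit, n_reps = 1, seed = 29)
  # a single replicate gives a degenerate interval equal to that replicate
  expect_equal(b1$ci$lower, b1$ci$upper)
  expect_equal(b1$ci$lower, b1$replicates$pse[1])
  # with more replicates the interval covers the point estimate
  b <- bootstrap_pse_ci(fit, n_reps = 100, seed = 30)
  expect_true(b$ci$lower < fit$pse && fit$pse < b$ci$upper)
})

test_that("likelihood ratio test compares nested slope models", {
  trials <- sim_probit_trials(0, 0.05, seq(-20, 20, 10), 30, seed = 31)
  trials$grp <- rep_len(c("a", "b"), nrow(trials))
  full <- glm(response ~ grp + v_surf:grp, binomial("probit"), data = trials)
  reduced <- glm(response ~ grp + v_surf, binomial("probit"), data = trials)
  out <- lrt_slopes(full, reduced)
  expect_equal(out$df, 1)
  expect_gte(out$statistic, 0)
  expect_true(out$p_value > 0 && out$p_value <= 1)

  same <- lrt_slopes(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt_slopes(reduced, full), "not nested")
})

test_that("discrimination fit recovers generative JNDs from interval data", {
  # choose tactile variances whose closed-form two-interval JNDs equal the
  # study's 5.9 (high) and 8.3 (low) mm/s, then check the refit recovers them
  jnd_2i <- function(s2t, s2_prior) {
    w <- s2_prior / (s2_prior + s2t)
    jnd_from_slope(w / sqrt(2 * (w^2 * s2t + w * s2t)))
  }
  s2_prior <- calibrate_prior_variance(0.02, 34)
  s2_high <- uniroot(function(x) jnd_2i(x, s2_prior) - 5.9, c(0.5, 30))$root
  s2_low <- uniroot(function(x) jnd_2i(x, s2_prior) - 8.3, c(0.5, 30))$root
  pp <- observer_params(sigma2_prop = 34, sigma2_tact = s2_high,
                        sigma2_prior_prop = s2_prior,
                        kappa_low_amp = s2_low / s2_high)
  tr <- simulate_observer_responses(pp, make_design("exp3", reps_exp3 = 100),
                                    seed = 32)
  fit_hi <- fit_discrimination(tr[tr$condition == "high_amp", ])
  fit_lo <- fit_discrimination(tr[tr$condition == "low_amp", ])
  expect_lt(abs(fit_hi$jnd - 5.9), 2 * fit_hi$jnd_se)
  expect_lt(abs(fit_lo$jnd - 8.3), 2 * fit_lo$jnd_se)
})

test_that("QC mirrors the exclusion rules as explicit flags", {
  d <- make_design("exp1", reps_main = 5, reps_control = 5)
  tr <- simulate_population(population_spec(2), d, seed = 33)
  # a constant responder and a reversed-slope responder
  const <- cbind(observer_id = "obs_const", d, response = 1L)[, names(tr)]
  rev_obs <- d
  set.seed(34)
  rev_obs$response <- rbinom(nrow(d), 1, pnorm(-0.08 * d$v_surf))
  rev_obs <- cbind(observer_id = "obs_rev", rev_obs)[, names(tr)]
  qc <- qc_trials(rbind(tr, const, rev_obs))
  expect_true(all(qc$constant_response[qc$observer_id == "obs_const"]))
  expect_true(any(qc$reversed_slope[qc$observer_id == "obs_rev"]))
  expect_false(any(qc$constant_response[qc$observer_id %in%
                                          c("obs01", "obs02")]))
})
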