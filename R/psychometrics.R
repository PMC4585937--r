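#' @importFrom stats pnorm qnorm coef vcov logLik pchisq aggregate quantile
NULL

# aggregate trial-level binary responses to binomial counts
aggregate_binary <- function(trials, by = "v_surf") {
  agg <- stats::aggregate(trials$response, trials[, by, drop = FALSE],
                          function(y) c(k = sum(y), n = length(y)))
  out <- cbind(agg[, by, drop = FALSE], as.data.frame(agg$x))
  out[do.call(order, out[, by, drop = FALSE]), , drop = FALSE]
}

# delta-method SE of a ratio-type transform g(b) with gradient grad at coef b
delta_se <- function(grad, vc) sqrt(drop(t(grad) %*% vc %*% grad))

#' Maximum-likelihood probit psychometric fit for one observer/condition
#'
#' Fits `P(response = 1) = pnorm(b0 + b1 * v_surf)` by maximum likelihood
#' (binomial probit GLM) and derives the point of subjective equality
#' `PSE = -b0/b1` and `JND = qnorm(0.75)/b1` with delta-method standard
#' errors. Degenerate data are flagged rather than silently fitted: complete
#' separation sets `flags$separation` (slope effectively infinite) and an
#' estimated slope indistinguishable from zero sets `flags$flat_slope` with
#' `pse = NA`. Constant responses (all 0 or all 1) are an error, mirroring the
#' chance-level exclusion rule of the behavioural analysis.
#'
#' @param trials data.frame with numeric `v_surf` and binary `response`
#'   columns; at least two distinct velocity levels.
#' @return An object of class `psychometric_fit`: coefficients, their
#'   covariance, `pse`, `pse_se`, `jnd`, `jnd_se`, `loglik`, `df`, `n_trials`,
#'   `flags`, and the underlying `glm` fit in `$model`.
#' @export
fit_probit_ml <- function(trials) {
  if (!all(c("v_surf", "response") %in% names(trials))) {
    stop("trials needs v_surf and response columns")
  }
  if (length(unique(trials$v_surf)) < 2) {
    stop("need at least two distinct velocity levels")
  }
  if (length(unique(trials$response)) < 2) {
    stop("constant response probability: all responses identical")
  }
  agg <- aggregate_binary(trials)
  warns <- character(0)
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ v_surf, family = stats::binomial("probit"),
               data = agg),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  vc <- vcov(fit)
  # perfect separation: zero residual deviance with fitted extremes (a
  # zero-deviance fit at interior probabilities is balanced, not separated)
  extreme <- any(pmin(fit$fitted.values, 1 - fit$fitted.values) < 1e-6)
  separation <- !fit$converged || (fit$deviance < 1e-8 && extreme) ||
    abs(b[2]) > 10
  flat <- !separation && abs(b[2]) < 1e-6
  pse <- if (separation || flat) NA_real_ else unname(-b[1] / b[2])
  pse_se <- if (is.na(pse)) NA_real_ else {
    delta_se(c(-1 / b[2], b[1] / b[2]^2), vc)
  }
  jnd <- if (!separation && !flat && b[2] > 0) {
    unname(qnorm(0.75) / b[2])
  } else NA_real_
  jnd_se <- if (is.na(jnd)) NA_real_ else {
    delta_se(c(0, -qnorm(0.75) / b[2]^2), vc)
  }
  structure(
    list(coefficients = c(intercept = unname(b[1]), slope = unname(b[2])),
         vcov = vc, pse = pse, pse_se = pse_se, jnd = jnd, jnd_se = jnd_se,
         loglik = as.numeric(logLik(fit)), df = 2L, n_trials = nrow(trials),
         data = agg,
         flags = list(separation = separation, flat_slope = flat,
                      converged = fit$converged, warnings = warns),
         model = fit),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Probit fit (%d trials): intercept %.4g, slope %.4g /(mm/s)\n",
    x$n_trials, x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  PSE %.4g +/- %.3g mm/s, JND %.4g +/- %.3g mm/s\n",
              x$pse, x$pse_se, x$jnd, x$jnd_se))
  if (x$flags$separation) cat("  [flagged: complete separation]\n")
  if (x$flags$flat_slope) cat("  [flagged: flat slope, PSE undefined]\n")
  invisible(x)
}

#' Hierarchical (mixed-effects) probit psychometric fit
#'
#' Fits all observers and conditions simultaneously with a probit GLMM:
#' condition-specific fixed intercept and slope, plus a bivariate-Gaussian
#' random intercept and slope per observer (shared across conditions). The
#' marginal likelihood is maximised with `lme4::glmer` (Laplace
#' approximation). Per-condition PSEs are derived from the fixed effects with
#' delta-method standard errors.
#'
#' @param trials trial records with `observer_id`, `condition`, `v_surf`,
#'   `response`; at least two observers.
#' @param common_slope if `TRUE`, fit a single slope shared by all conditions
#'   (the reduced model of the slope likelihood-ratio test).
#' @return An object of class `hierarchical_fit`: `fixed` (data.frame with
#'   condition, intercept, slope, pse, pse_se), `re_cov` (2x2 random-effect
#'   covariance), `loglik`, `df`, `n_obs`, convergence diagnostics, the
#'   aggregated data and the `merMod` object in `$model`.
#' @export
fit_hierarchical_probit <- function(trials, common_slope = FALSE) {
  need <- c("observer_id", "condition", "v_surf", "response")
  if (!all(need %in% names(trials))) stop("trials lacks canonical columns")
  if (length(unique(trials$observer_id)) < 2) stop("need >= 2 observers")
  agg <- aggregate_binary(trials, by = c("observer_id", "condition", "v_surf"))
  agg$condition <- factor(agg$condition)
  form <- if (common_slope) {
    cbind(k, n - k) ~ 0 + condition + v_surf + (1 + v_surf | observer_id)
  } else {
    cbind(k, n - k) ~ 0 + condition + condition:v_surf +
      (1 + v_surf | observer_id)
  }
  msgs <- character(0)
  collect <- function(expr) {
    withCallingHandlers(
      expr,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
  }
  fit <- collect(lme4::glmer(form, data = agg,
                             family = stats::binomial("probit")))
  b <- lme4::fixef(fit)
  vc <- collect(as.matrix(vcov(fit)))
  conds <- levels(agg$condition)
  fixed <- do.call(rbind, lapply(conds, function(cc) {
    i0 <- match(paste0("condition", cc), names(b))
    i1 <- if (common_slope) match("v_surf", names(b)) else {
      match(paste0("condition", cc, ":v_surf"), names(b))
    }
    g <- rep(0, length(b))
    g[i0] <- -1 / b[i1]
    g[i1] <- b[i0] / b[i1]^2
    data.frame(condition = cc, intercept = unname(b[i0]),
               slope = unname(b[i1]), pse = unname(-b[i0] / b[i1]),
               pse_se = delta_se(g, vc))
  }))
  re <- matrix(as.numeric(lme4::VarCorr(fit)$observer_id), 2, 2,
               dimnames = list(c("intercept", "v_surf"),
                               c("intercept", "v_surf")))
  structure(
    list(fixed = fixed, re_cov = re, loglik = as.numeric(logLik(fit)),
         df = attr(logLik(fit), "df"), n_obs = length(unique(agg$observer_id)),
         common_slope = common_slope,
         diagnostics = list(messages = msgs,
                            singular = lme4::isSingular(fit)),
         data = agg, model = fit),
    class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat(sprintf("Hierarchical probit fit (%d observers, logLik %.2f):\n",
              x$n_obs, x$loglik))
  print(x$fixed, row.names = FALSE)
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for the PSE
#'
#' Simulates responses from the fitted model, refits, and collects the PSEs
#' across replicates; reports percentile 95% intervals per condition and (for
#' hierarchical fits with exactly two conditions) for the between-condition
#' PSE difference. For a `hierarchical_fit`, each replicate redraws the
#' per-observer random effects from the fitted bivariate Gaussian and the
#' binomial responses from the fitted fixed effects, then refits the GLMM.
#' For a single `psychometric_fit`, each replicate redraws binomial counts at
#' the fitted probabilities and refits the probit GLM. Replicates whose refit
#' fails are excluded and counted.
#'
#' @param fit a `hierarchical_fit` or `psychometric_fit`.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return An object of class `bootstrap_result`: `point` (named estimates),
#'   `replicates` (data.frame, one row per successful replicate), `ci`
#'   (data.frame with quantity, lower, upper), `n_reps`, `n_failed`, `seed`.
#' @export
bootstrap_pse_ci <- function(fit, n_reps = 1000, seed = 1L, ...) {
  UseMethod("bootstrap_pse_ci")
}

percentile_ci <- function(x) {
  q <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' @export
bootstrap_pse_ci.hierarchical_fit <- function(fit, n_reps = 1000, seed = 1L,
                                              ...) {
  set.seed(seed)
  agg <- fit$data
  obs <- unique(agg$observer_id)
  fe <- fit$fixed
  idx <- match(agg$condition, fe$condition)
  reps <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    u <- MASS::mvrnorm(length(obs), mu = c(0, 0), Sigma = fit$re_cov)
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    io <- match(agg$observer_id, obs)
    eta <- (fe$intercept[idx] + u[io, 1]) +
      (fe$slope[idx] + u[io, 2]) * agg$v_surf
    sim <- agg
    sim$k <- stats::rbinom(nrow(agg), agg$n, pnorm(eta))
    refit <- tryCatch({
      trials <- sim[rep(seq_len(nrow(sim)), sim$n), ]
      trials$response <- unlist(lapply(seq_len(nrow(sim)), function(i) {
        rep(c(1L, 0L), c(sim$k[i], sim$n[i] - sim$k[i]))
      }))
      fit_hierarchical_probit(trials, common_slope = fit$common_slope)
    }, error = function(e) NULL)
    if (is.null(refit)) {
      n_failed <- n_failed + 1L
      next
    }
    pses <- stats::setNames(refit$fixed$pse, refit$fixed$condition)
    reps[[r]] <- as.data.frame(as.list(pses))
  }
  replicates <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  point <- stats::setNames(fe$pse, fe$condition)
  if (ncol(replicates) == 2) {
    dname <- paste(names(replicates)[1], "-", names(replicates)[2])
    replicates[[dname]] <- replicates[[1]] - replicates[[2]]
    point[dname] <- point[1] - point[2]
  }
  ci <- do.call(rbind, lapply(names(replicates), function(nm) {
    q <- percentile_ci(replicates[[nm]])
    data.frame(quantity = nm, lower = q["lower"], upper = q["upper"])
  }))
  rownames(ci) <- NULL
  structure(list(point = point, replicates = replicates, ci = ci,
                 n_reps = n_reps, n_failed = n_failed, seed = seed),
            class = "bootstrap_result")
}

#' @export
bootstrap_pse_ci.psychometric_fit <- function(fit, n_reps = 1000, seed = 1L,
                                              ...) {
  set.seed(seed)
  agg <- fit$data
  b <- fit$coefficients
  p_hat <- pnorm(b[1] + b[2] * agg$v_surf)
  pses <- rep(NA_real_, n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    sim <- agg
    sim$k <- stats::rbinom(nrow(agg), agg$n, p_hat)
    refit <- tryCatch(
      stats::glm(cbind(k, n - k) ~ v_surf, family = stats::binomial("probit"),
                 data = sim),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(cbind(k, n - k) ~ v_surf,
                                    family = stats::binomial("probit"),
                                    data = sim))
      })
    if (is.null(refit) || !refit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    bb <- coef(refit)
    pses[r] <- -bb[1] / bb[2]
  }
  replicates <- data.frame(pse = pses[!is.na(pses)])
  q <- percentile_ci(replicates$pse)
  structure(list(point = c(pse = fit$pse), replicates = replicates,
                 ci = data.frame(quantity = "pse", lower = q["lower"],
                                 upper = q["upper"], row.names = NULL),
                 n_reps = n_reps, n_failed = n_failed, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Parametric bootstrap (%d reps, %d failed):\n",
              x$n_reps, x$n_failed))
  tab <- x$ci
  tab$point <- x$point[match(tab$quantity, names(x$point))]
  print(tab[, c("quantity", "point", "lower", "upper")], row.names = FALSE)
  invisible(x)
}

#' Percentile CI of a between-condition PSE difference
#'
#' Extracts the bootstrap distribution of `PSE[cond_a] - PSE[cond_b]` from a
#' [bootstrap_pse_ci()] result on a hierarchical fit. The difference is
#' significant at the 5% level when the interval excludes zero.
#'
#' @param boot a `bootstrap_result` with per-condition replicates.
#' @param cond_a,cond_b condition labels (default: the first two columns).
#' @return List with `estimate`, `lower`, `upper`, `excludes_zero`.
#' @export
pse_difference_ci <- function(boot, cond_a = NULL, cond_b = NULL) {
  stopifnot(inherits(boot, "bootstrap_result"))
  reps <- boot$replicates
  if (is.null(cond_a)) cond_a <- names(reps)[1]
  if (is.null(cond_b)) cond_b <- names(reps)[2]
  if (!all(c(cond_a, cond_b) %in% names(reps))) {
    stop("conditions not found in bootstrap replicates")
  }
  d <- reps[[cond_a]] - reps[[cond_b]]
  q <- percentile_ci(d)
  est <- unname(boot$point[cond_a] - boot$point[cond_b])
  list(estimate = est, lower = unname(q["lower"]), upper = unname(q["upper"]),
       excludes_zero = unname(q["lower"] > 0 || q["upper"] < 0))
}

# log-likelihood and parameter count for the model objects used here
loglik_df <- function(fit) {
  if (inherits(fit, "psychometric_fit") || inherits(fit, "hierarchical_fit")) {
    list(ll = fit$loglik, df = fit$df,
         n = if (!is.null(fit$data)) sum(fit$data$n) else NA)
  } else {
    ll <- logLik(fit)
    list(ll = as.numeric(ll), df = attr(ll, "df"), n = attr(ll, "nobs"))
  }
}

#' Likelihood-ratio test between nested psychometric models
#'
#' Compares a full and a reduced model fitted to the same data:
#' `statistic = 2 * (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in parameter
#' count. Used to test whether the psychometric slope differs between
#' conditions (e.g. high vs low pin-oscillation amplitude).
#'
#' @param fit_full,fit_reduced nested fits (`glm`, `merMod`,
#'   `psychometric_fit` or `hierarchical_fit`); the reduced model must have
#'   fewer or equally many parameters.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_slopes <- function(fit_full, fit_reduced) {
  f <- loglik_df(fit_full)
  r <- loglik_df(fit_reduced)
  if (!is.na(f$n) && !is.na(r$n) && f$n != r$n) {
    stop("models were not fitted to the same data")
  }
  df <- f$df - r$df
  if (df < 0) stop("fit_full has fewer parameters than fit_reduced: not nested")
  stat <- max(0, 2 * (f$ll - r$ll))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Probit fit of a two-interval speed-discrimination task
#'
#' Fits the probability of reporting the comparison interval as faster against
#' the signed comparison-minus-standard speed difference (stored in `v_surf`),
#' and reports the JND. With a symmetric design the fitted point of equality
#' is near zero.
#'
#' @param trials exp3-style trial records (one amplitude condition) with
#'   `v_surf` = signed speed difference and binary `response`.
#' @return A `psychometric_fit` (see [fit_probit_ml()]).
#' @export
fit_discrimination <- function(trials) {
  fit_probit_ml(trials)
}

#' Data-quality flags per observer and condition
#'
#' Mirrors the behavioural exclusion rules as explicit flags rather than
#' silent drops: a constant response pattern (chance-level or fixed
#' responding) and a significantly reversed (negative) psychometric slope.
#'
#' @param trials trial records with `observer_id`, `condition`, `v_surf`,
#'   `response`.
#' @return data.frame with one row per observer-condition and logical columns
#'   `constant_response` and `reversed_slope`.
#' @export
qc_trials <- function(trials) {
  cells <- unique(trials[, c("observer_id", "condition")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$observer_id == cells$observer_id[i] &
                    trials$condition == cells$condition[i], ]
    constant <- length(unique(sub$response)) < 2
    reversed <- FALSE
    if (!constant) {
      fit <- tryCatch(fit_probit_ml(sub), error = function(e) NULL)
      if (!is.null(fit) && !fit$flags$separation) {
        b1 <- fit$coefficients["slope"]
        se1 <- sqrt(fit$vcov[2, 2])
        reversed <- unname(b1 + 2 * se1 < 0)
      }
    }
    data.frame(observer_id = cells$observer_id[i],
               condition = cells$condition[i],
               constant_response = constant, reversed_slope = reversed)
  })
  do.call(rbind, out)
}
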