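#' Negative log-likelihood of the Bayesian observer model
#'
#' Bernoulli negative log-likelihood of trial-level binary responses under the
#' stationarity-prior observer: each trial's away-probability comes from
#' [response_probability()], with control trials discarding the proprioceptive
#' channel and low-amplitude trials inflating the tactile variance by
#' `kappa_low_amp`. Probabilities are clamped to `[1e-12, 1 - 1e-12]` for
#' numerical stability; the number of clamped cells is attached as the
#' `n_clamped` attribute.
#'
#' @param params an [observer_params()] object.
#' @param trials trial records with `condition`, `v_surf`, `v_prop`,
#'   `amplitude`, `response`.
#' @return Scalar negative log-likelihood (attribute `n_clamped`).
#' @export
negloglik_observer_model <- function(params, trials) {
  stopifnot(inherits(params, "observer_params"))
  need <- c("condition", "v_surf", "v_prop", "amplitude", "response")
  if (!all(need %in% names(trials))) stop("trials lacks canonical columns")
  nll_cells(params, trial_cells(trials))
}

# collapse trials to unique stimulus cells with binomial counts
trial_cells <- function(trials) {
  low <- is_low_amplitude(trials$amplitude)
  key <- interaction(trials$condition, trials$v_surf, trials$v_prop, low,
                     drop = TRUE)
  first <- !duplicated(key)
  labels <- as.character(key[first])
  ks <- rowsum(trials$response, key)
  ns <- table(key)
  data.frame(condition = trials$condition[first],
             v_surf = trials$v_surf[first],
             v_prop = trials$v_prop[first],
             low = low[first],
             k = ks[labels, 1],
             n = as.vector(ns[labels]))
}

# Bernoulli NLL over pre-aggregated cells
nll_cells <- function(params, cells) {
  p <- vapply(seq_len(nrow(cells)), function(i) {
    response_probability(params, cells$v_surf[i], v_prop = cells$v_prop[i],
                         proprioception_active = cells$condition[i] != "control",
                         low_amplitude = cells$low[i])
  }, numeric(1))
  n_clamped <- sum(p < 1e-12 | p > 1 - 1e-12)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  nll <- -sum(cells$k * log(p) + (cells$n - cells$k) * log1p(-p))
  attr(nll, "n_clamped") <- n_clamped
  nll
}

#' Fit the Bayesian observer model by constrained maximum likelihood
#'
#' Estimates the proprioceptive and tactile likelihood variances by bounded,
#' derivative-free maximum likelihood, with the prior variance held fixed at
#' `sigma2_prior` (the model's likelihood is nearly flat along directions that
#' trade prior against likelihood variance, so the prior is constrained and
#' the identifiable quantity is the variance ratio). The search runs on the
#' log-variance scale from several starting points to guard against the flat
#' directions. Data containing only control trials identify only the tactile
#' variance; the proprioceptive variance is then fixed at its starting value.
#'
#' @param trials trial records (canonical columns; both conditions for the
#'   full model).
#' @param sigma2_prior fixed prior variance (mm^2/s^2). Default 0.4753, the
#'   value calibrated from a proprioceptive-only probit slope of 0.02 at
#'   likelihood variance 34 mm^2/s^2.
#' @param start optional length-2 numeric `c(sigma2_prop, sigma2_tact)`
#'   starting values; a deterministic spread of starts is added.
#' @param bounds length-2 search bounds on each variance (mm^2/s^2).
#' @param n_starts number of starting points.
#' @return An object of class `bayes_fit`: `sigma2_prop`, `sigma2_tact`,
#'   `ratio` (prop/tact), `sigma2_prior`, `loglik`, `n_clamped`, predicted
#'   per-condition psychometric parameters (`$predicted$main`,
#'   `$predicted$control`; the control PSE is structurally 0), `v_pursuit`,
#'   convergence table of the starts.
#' @export
fit_observer_model <- function(trials, sigma2_prior = 0.4753, start = NULL,
                               bounds = c(1e-2, 1e4), n_starts = 5) {
  need <- c("condition", "v_surf", "v_prop", "amplitude", "response")
  if (!all(need %in% names(trials))) stop("trials lacks canonical columns")
  vp <- unique(trials$v_prop[trials$condition != "control"])
  vp <- vp[vp != 0]
  control_only <- length(vp) == 0
  v_pursuit <- if (control_only) 10.8 else vp[1]
  lb <- log(bounds)
  cells <- trial_cells(trials)

  make_params <- function(s2p, s2t) {
    observer_params(sigma2_prop = s2p, sigma2_tact = s2t,
                    sigma2_prior_prop = sigma2_prior,
                    v_pursuit = v_pursuit, kappa_low_amp = 1)
  }

  if (control_only) {
    obj1 <- function(lt) {
      as.numeric(nll_cells(make_params(34, exp(lt)), cells))
    }
    opt <- stats::optimize(obj1, interval = lb)
    s2t <- exp(opt$minimum)
    est <- make_params(34, s2t)
    nll <- nll_cells(est, cells)
    conv <- data.frame(start_prop = NA, start_tact = NA,
                       nll = as.numeric(nll), convergence = 0L)
    s2p <- NA_real_
  } else {
    obj <- function(lpar) {
      if (any(lpar < lb[1]) || any(lpar > lb[2])) return(1e10)
      as.numeric(nll_cells(make_params(exp(lpar[1]), exp(lpar[2])), cells))
    }
    starts <- list(c(34, 11), c(10, 10), c(100, 5), c(5, 30), c(60, 60),
                   c(200, 20), c(20, 2))
    if (!is.null(start)) starts <- c(list(start), starts)
    starts <- starts[seq_len(min(n_starts, length(starts)))]
    fits <- lapply(starts, function(s) {
      tryCatch(stats::optim(log(s), obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      stop("observer-model fit failed to converge from every start")
    }
    fits <- fits[ok]
    starts <- starts[ok]
    vals <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(vals)]]
    s2p <- exp(best$par[1])
    s2t <- exp(best$par[2])
    est <- make_params(s2p, s2t)
    nll <- nll_cells(est, cells)
    conv <- data.frame(
      start_prop = vapply(starts, `[`, numeric(1), 1),
      start_tact = vapply(starts, `[`, numeric(1), 2),
      nll = vals,
      convergence = vapply(fits, `[[`, numeric(1), "convergence"))
  }
  structure(
    list(sigma2_prop = unname(s2p), sigma2_tact = unname(s2t),
         ratio = unname(s2p / s2t), sigma2_prior = sigma2_prior,
         loglik = -as.numeric(nll), n_clamped = attr(nll, "n_clamped"),
         predicted = list(main = predicted_psychometric(est, "main"),
                          control = predicted_psychometric(est, "control")),
         v_pursuit = v_pursuit, n_trials = nrow(trials), starts = conv),
    class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("Bayesian observer fit (prior variance fixed at",
      format(x$sigma2_prior), "mm^2/s^2):\n")
  cat(sprintf("  sigma2_prop %.4g, sigma2_tact %.4g (ratio %.3g), logLik %.2f\n",
              x$sigma2_prop, x$sigma2_tact, x$ratio, x$loglik))
  cat(sprintf("  predicted PSE: main %.3g mm/s, control %.3g mm/s\n",
              x$predicted$main$pse, x$predicted$control$pse))
  invisible(x)
}

#' Parametric-bootstrap population fit of the observer model
#'
#' The population-level fitting procedure: given descriptive probit intercepts
#' and slopes per condition, each replicate (i) simulates per-level binomial
#' response counts from those psychometric functions
#' ([simulate_binomial_from_probit()]), (ii) fits the constrained observer
#' model to the simulated session, and (iii) records the estimated variances
#' and the model-predicted main-task PSE. Percentile 95% intervals summarise
#' the replicate distribution; replicate fit failures are excluded and
#' counted.
#'
#' @param b_main,b_control numeric length-2 `c(intercept, slope)` of the
#'   descriptive probit fit in each condition (e.g. slope from the
#'   hierarchical fit with the intercept set from the estimated PSE).
#' @param velocities_main,velocities_control stimulus levels per condition.
#' @param n_per_level trials per level.
#' @param n_reps bootstrap replicates (1000 for a full run).
#' @param seed integer seed.
#' @param sigma2_prior fixed prior variance passed to [fit_observer_model()].
#' @param v_pursuit mean pursuit velocity of the simulated main task, mm/s.
#' @param n_starts optimiser starts per replicate.
#' @return An object of class `bootstrap_fit`: `replicates` (data.frame with
#'   sigma2_prop, sigma2_tact, ratio, pse_main), `ci` (percentile bounds),
#'   `point` (medians), `n_reps`, `n_failed`, `seed`.
#' @export
parametric_bootstrap_fit <- function(b_main, b_control,
                                     velocities_main = seq(-30, 30, by = 10),
                                     velocities_control =
                                       setdiff(seq(-30, 30, by = 10), 0),
                                     n_per_level = 15, n_reps = 1000,
                                     seed = 1L, sigma2_prior = 0.4753,
                                     v_pursuit = 10.8, n_starts = 3) {
  set.seed(seed)
  cols <- c("sigma2_prop", "sigma2_tact", "ratio", "pse_main")
  reps <- matrix(NA_real_, n_reps, length(cols),
                 dimnames = list(NULL, cols))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cm <- simulate_binomial_from_probit(b_main[1], b_main[2],
                                        velocities_main, n_per_level)
    cc <- simulate_binomial_from_probit(b_control[1], b_control[2],
                                        velocities_control, n_per_level)
    trials <- rbind(
      expand_binomial_counts(cm, "main", v_prop = v_pursuit),
      expand_binomial_counts(cc, "control", v_prop = 0))
    fit <- tryCatch(
      fit_observer_model(trials, sigma2_prior = sigma2_prior,
                         n_starts = n_starts),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[r, ] <- c(fit$sigma2_prop, fit$sigma2_tact, fit$ratio,
                   fit$predicted$main$pse)
  }
  replicates <- as.data.frame(reps[stats::complete.cases(reps), , drop = FALSE])
  ci <- do.call(rbind, lapply(cols, function(nm) {
    q <- percentile_ci(replicates[[nm]])
    data.frame(quantity = nm, lower = q["lower"], upper = q["upper"])
  }))
  rownames(ci) <- NULL
  structure(list(replicates = replicates,
                 point = vapply(replicates, stats::median, numeric(1)),
                 ci = ci, n_reps = n_reps, n_failed = n_failed, seed = seed),
            class = "bootstrap_fit")
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  cat(sprintf("Observer-model parametric bootstrap (%d reps, %d failed):\n",
              x$n_reps, x$n_failed))
  tab <- x$ci
  tab$median <- x$point[match(tab$quantity, names(x$point))]
  print(tab[, c("quantity", "median", "lower", "upper")], row.names = FALSE)
  invisible(x)
}
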