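#' Build the stimulus design of a synthetic experiment
#'
#' Trial lists emulating the three behavioural tasks:
#'
#' * `exp1` — direction judgements during pursuit. 105 main-task trials (7
#'   velocities from -30 to 30 mm/s including 0, 15 repetitions) and 90
#'   control-task trials (6 nonzero velocities, 15 repetitions), each block
#'   shuffled.
#' * `exp2` — pursuit with high/low pin-oscillation amplitude randomly
#'   intermixed in a single 200-trial block (5 velocities x 2 amplitudes x 20).
#' * `exp3` — two-interval speed discrimination with a stationary hand; one
#'   interval at the standard speed, the other offset by a signed difference
#'   (stored in `v_surf`; the standard in `v_std`), 2 amplitudes x 8
#'   differences x 12 repetitions.
#'
#' Velocity levels and repetition counts are overridable; the defaults factor
#' the published trial totals.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param seed integer seed controlling the trial shuffle.
#' @param v_pursuit phase-2 mean finger velocity in pursuit conditions, mm/s.
#' @param amplitude_high,amplitude_low pin oscillation amplitudes, mm.
#' @param velocities_main,reps_main exp1 main-task velocity levels (must
#'   include 0) and repetitions per level.
#' @param velocities_control,reps_control exp1 control-task levels (must not
#'   include 0) and repetitions.
#' @param velocities_exp2,reps_exp2 exp2 levels and repetitions per
#'   level-amplitude cell.
#' @param v_standard,diffs_exp3,reps_exp3 exp3 standard speed (mm/s), signed
#'   comparison-minus-standard differences, repetitions per cell.
#' @return A data.frame with columns `experiment`, `condition`, `v_surf`,
#'   `v_prop`, `amplitude` (plus `v_std` for exp3), one row per trial.
#' @export
#' @examples
#' nrow(make_design("exp1"))  # 195
make_design <- function(experiment = c("exp1", "exp2", "exp3"), seed = 1L,
                        v_pursuit = 10.8,
                        amplitude_high = 0.1, amplitude_low = 0.04,
                        velocities_main = seq(-30, 30, by = 10),
                        reps_main = 15L,
                        velocities_control = setdiff(seq(-30, 30, by = 10), 0),
                        reps_control = 15L,
                        velocities_exp2 = seq(-20, 20, by = 10),
                        reps_exp2 = 20L,
                        v_standard = 30,
                        diffs_exp3 = c(-15, -10, -5, -2.5, 2.5, 5, 10, 15),
                        reps_exp3 = 12L) {
  experiment <- match.arg(experiment)
  shuffle <- function(d) d[sample.int(nrow(d)), , drop = FALSE]
  set.seed(seed)
  out <- switch(
    experiment,
    exp1 = {
      if (any(velocities_control == 0)) {
        stop("control velocities must not include 0")
      }
      if (!any(velocities_main == 0)) {
        stop("main velocities must include 0")
      }
      main <- data.frame(condition = "main",
                         v_surf = rep(velocities_main, each = reps_main),
                         v_prop = v_pursuit, amplitude = amplitude_high)
      ctrl <- data.frame(condition = "control",
                         v_surf = rep(velocities_control, each = reps_control),
                         v_prop = 0, amplitude = amplitude_high)
      rbind(shuffle(main), shuffle(ctrl))  # separate blocks, shuffled within
    },
    exp2 = {
      cells <- expand.grid(v_surf = velocities_exp2,
                           amplitude = c(amplitude_high, amplitude_low))
      d <- cells[rep(seq_len(nrow(cells)), each = reps_exp2), ]
      d$condition <- ifelse(d$amplitude >= amplitude_high, "high_amp", "low_amp")
      d$v_prop <- v_pursuit
      shuffle(d[, c("condition", "v_surf", "v_prop", "amplitude")])
    },
    exp3 = {
      cells <- expand.grid(v_surf = diffs_exp3,
                           amplitude = c(amplitude_high, amplitude_low))
      d <- cells[rep(seq_len(nrow(cells)), each = reps_exp3), ]
      d$condition <- ifelse(d$amplitude >= amplitude_high, "high_amp", "low_amp")
      d$v_prop <- 0
      d$v_std <- v_standard
      shuffle(d[, c("condition", "v_surf", "v_prop", "amplitude", "v_std")])
    })
  out <- cbind(experiment = experiment, out)
  rownames(out) <- NULL
  out
}

# low-amplitude indicator relative to the largest amplitude present
is_low_amplitude <- function(amplitude) {
  amplitude < max(amplitude) - 1e-12
}

#' Simulate one observer's binary responses from the Bayesian model
#'
#' Forward-simulates the generative observer: for direction judgements each
#' response is Bernoulli with `p = response_probability(...)` (control trials
#' discard proprioception; low-amplitude trials inflate the tactile variance by
#' `kappa_low_amp`). For two-interval discrimination (exp3) each interval's
#' perceived speed is simulated explicitly as a two-stage draw (noisy tactile
#' measurement, then a sample from its posterior) and the response indicates
#' which interval's draw was larger.
#'
#' @param params an [observer_params()] generative observer.
#' @param design a [make_design()] trial table.
#' @param seed integer seed; identical seeds give identical responses.
#' @param observer_id label stored in the output.
#' @return The design with `observer_id` and binary `response` columns
#'   appended (1 = "away" / "second interval faster").
#' @export
simulate_observer_responses <- function(params, design, seed = 1L,
                                        observer_id = "obs01") {
  stopifnot(inherits(params, "observer_params"))
  if (!all(c("condition", "v_surf", "v_prop", "amplitude") %in% names(design))) {
    stop("design lacks canonical columns")
  }
  set.seed(seed)
  n <- nrow(design)
  low <- is_low_amplitude(design$amplitude)
  if (!is.null(design$v_std)) {
    # two-interval discrimination: two-stage sample per interval
    draw_perceived <- function(v, low_amp) {
      s2t <- tact_variance(params, low_amp)
      ch <- shrinkage_weight(params$sigma2_prior_tact, s2t)
      m <- stats::rnorm(length(v), mean = v, sd = sqrt(s2t))
      stats::rnorm(length(v), mean = ch$weight * m, sd = sqrt(ch$post_var))
    }
    p_std <- draw_perceived(design$v_std, low)
    p_cmp <- draw_perceived(design$v_std + design$v_surf, low)
    response <- as.integer(p_cmp > p_std)
  } else {
    p <- vapply(seq_len(n), function(i) {
      response_probability(params, design$v_surf[i], v_prop = design$v_prop[i],
                           proprioception_active = design$condition[i] != "control",
                           low_amplitude = low[i])
    }, numeric(1))
    response <- stats::rbinom(n, 1L, p)
  }
  cbind(observer_id = observer_id, design, response = response)
}

#' Specification of a heterogeneous observer population
#'
#' Population-level generative model of the hierarchical (mixed-effects)
#' psychometric analysis: per-condition fixed intercept/slope plus a
#' per-observer random intercept/slope pair drawn from a bivariate Gaussian.
#'
#' @param n_observers number of observers (>= 1).
#' @param fixed_effects data.frame with columns `condition`, `intercept`
#'   (probit units), `slope` (probit units per mm/s). The default encodes the
#'   study's group-level estimates: PSE 6.8 mm/s in the main task (slope
#'   0.0425) and -1.6 mm/s in the control task (slope 0.0601).
#' @param re_covariance symmetric positive semi-definite 2x2 covariance of the
#'   random (intercept, slope) pair. The default gives a per-observer PSE
#'   spread of roughly 3.5 mm/s and no intercept-slope correlation.
#' @param seed default seed used by [simulate_population()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_observers = 10,
                            fixed_effects = data.frame(
                              condition = c("main", "control"),
                              intercept = c(-6.8 * 0.0425, 1.6 * 0.0601),
                              slope = c(0.0425, 0.0601)),
                            re_covariance = diag(c(0.15^2, 0.008^2)),
                            seed = 1L) {
  if (n_observers < 1) stop("need at least one observer")
  if (!all(c("condition", "intercept", "slope") %in% names(fixed_effects))) {
    stop("fixed_effects needs condition, intercept, slope columns")
  }
  if (!isTRUE(all.equal(re_covariance, t(re_covariance))) ||
      any(eigen(re_covariance, symmetric = TRUE,
                only.values = TRUE)$values < -1e-10)) {
    stop("re_covariance must be symmetric positive semi-definite")
  }
  structure(list(n_observers = as.integer(n_observers),
                 fixed_effects = fixed_effects,
                 re_covariance = re_covariance, seed = seed),
            class = "population_spec")
}

#' Simulate a population of observers under the hierarchical probit model
#'
#' For each observer draws a random (intercept, slope) deviation from the
#' bivariate Gaussian of the [population_spec()], then draws each binary
#' response with `p = pnorm((theta0 + u0) + (theta1 + u1) * v_surf)` using the
#' condition-specific fixed effects.
#'
#' @param spec a [population_spec()].
#' @param design a [make_design()] trial table (one observer's session; it is
#'   replicated for every observer).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return Trial records for all observers (design columns plus `observer_id`
#'   and `response`).
#' @export
simulate_population <- function(spec, design, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  zero_re <- all(spec$re_covariance == 0)
  fe <- spec$fixed_effects
  idx <- match(design$condition, fe$condition)
  if (anyNA(idx)) stop("design has conditions absent from fixed_effects")
  out <- vector("list", spec$n_observers)
  for (i in seq_len(spec$n_observers)) {
    u <- if (zero_re) c(0, 0) else {
      MASS::mvrnorm(1, mu = c(0, 0), Sigma = spec$re_covariance)
    }
    eta <- (fe$intercept[idx] + u[1]) + (fe$slope[idx] + u[2]) * design$v_surf
    resp <- stats::rbinom(nrow(design), 1L, stats::pnorm(eta))
    out[[i]] <- cbind(observer_id = sprintf("obs%02d", i), design,
                      response = resp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate binomial response counts from a probit psychometric function
#'
#' Per velocity level draws `k ~ Binomial(n, pnorm(b0 + b1 * v))`; the
#' simulation primitive of the parametric bootstrap.
#'
#' @param b0,b1 probit intercept and slope.
#' @param velocities velocity levels, mm/s.
#' @param n_per_level trials per level (>= 1).
#' @param seed optional integer seed (`NULL` leaves the RNG stream untouched).
#' @return data.frame with `v_surf`, `n`, `k` and the generative `p`.
#' @export
simulate_binomial_from_probit <- function(b0, b1, velocities, n_per_level,
                                          seed = NULL) {
  if (n_per_level < 1) stop("n_per_level must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::pnorm(b0 + b1 * velocities)
  data.frame(v_surf = velocities, n = n_per_level,
             k = stats::rbinom(length(velocities), n_per_level, p), p = p)
}

# expand per-level binomial counts into canonical trial rows
expand_binomial_counts <- function(counts, condition, v_prop,
                                   amplitude = 0.1, observer_id = "boot",
                                   experiment = "exp1") {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    k <- counts$k[i]
    data.frame(observer_id = observer_id, experiment = experiment,
               condition = condition, v_surf = counts$v_surf[i],
               v_prop = v_prop, amplitude = amplitude,
               response = rep(c(1L, 0L), c(k, n - k)))
  })
  do.call(rbind, rows)
}
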