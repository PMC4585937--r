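#' Parameters of the Bayesian stationarity-prior observer
#'
#' Bundles the generative parameters of the ideal-observer model of tactile
#' motion perception during pursuit. The observer estimates the world-centred
#' surface velocity as the sum of two posterior samples: one for the initial
#' (pursuit) velocity, based on a proprioceptive measurement, and one for the
#' velocity change, based on a cutaneous (tactile slip) measurement. Each
#' measurement is combined with a zero-mean Gaussian stationarity prior before
#' summation; the asymmetry in likelihood noise between the two channels is
#' what produces the pursuit-dependent motion bias.
#'
#' By default the two channels share a single prior variance
#' (`sigma2_prior_tact = sigma2_prior_prop`), which is the single-prior model;
#' supplying different values gives the two-prior extension in which the priors
#' over absolute velocity and velocity change have different spreads.
#'
#' @param sigma2_prop proprioceptive likelihood variance (mm^2/s^2).
#' @param sigma2_tact tactile likelihood variance (mm^2/s^2) at the reference
#'   (high) pin-oscillation amplitude.
#' @param sigma2_prior_prop variance (mm^2/s^2) of the zero-mean stationarity
#'   prior applied to the initial-velocity (proprioceptive) estimate. The
#'   default is the value calibrated so that the predicted proprioceptive-only
#'   probit slope equals 0.02 when `sigma2_prop = 34` (see
#'   [calibrate_prior_variance()]).
#' @param sigma2_prior_tact prior variance for the velocity-change (tactile)
#'   estimate; defaults to `sigma2_prior_prop` (single-prior model).
#' @param v_pursuit mean pursuit (finger) velocity in mm/s, positive away from
#'   the body.
#' @param kappa_low_amp multiplicative factor (>= 1) applied to `sigma2_tact`
#'   in the low pin-oscillation-amplitude condition, modelling the reduced
#'   tactile signal-to-noise ratio.
#'
#' @return An object of class `observer_params`.
#' @seealso [fused_distribution()], [predicted_psychometric()]
#' @export
#' @examples
#' observer_params()                      # calibrated defaults
#' observer_params(sigma2_prop = 20, sigma2_tact = 20)  # no noise asymmetry
observer_params <- function(sigma2_prop = 34,
                            sigma2_tact = 11,
                            sigma2_prior_prop = 0.4753,
                            sigma2_prior_tact = sigma2_prior_prop,
                            v_pursuit = 10.8,
                            kappa_low_amp = 2) {
  vars <- c(sigma2_prop = sigma2_prop, sigma2_tact = sigma2_tact,
            sigma2_prior_prop = sigma2_prior_prop,
            sigma2_prior_tact = sigma2_prior_tact)
  if (any(!is.finite(vars)) || any(vars <= 0)) {
    stop("all variances must be finite and strictly positive")
  }
  if (!is.finite(kappa_low_amp) || kappa_low_amp < 1) {
    stop("kappa_low_amp must be finite and >= 1")
  }
  if (!is.finite(v_pursuit)) stop("v_pursuit must be finite")
  structure(
    list(sigma2_prop = sigma2_prop,
         sigma2_tact = sigma2_tact,
         sigma2_prior_prop = sigma2_prior_prop,
         sigma2_prior_tact = sigma2_prior_tact,
         v_pursuit = v_pursuit,
         kappa_low_amp = kappa_low_amp),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Bayesian observer parameters (mm^2/s^2 unless noted):\n")
  cat(sprintf("  likelihoods: proprioceptive %.4g, tactile %.4g (x %.3g low amp)\n",
              x$sigma2_prop, x$sigma2_tact, x$kappa_low_amp))
  two <- x$sigma2_prior_prop != x$sigma2_prior_tact
  cat(sprintf("  stationarity prior: %s%.4g%s\n",
              if (two) "prop " else "", x$sigma2_prior_prop,
              if (two) sprintf(", tact %.4g", x$sigma2_prior_tact) else ""))
  cat(sprintf("  pursuit velocity: %.3g mm/s\n", x$v_pursuit))
  invisible(x)
}

# effective tactile likelihood variance for a given amplitude condition
tact_variance <- function(params, low_amplitude = FALSE) {
  params$sigma2_tact * ifelse(low_amplitude, params$kappa_low_amp, 1)
}

#' Prior-likelihood shrinkage for one velocity channel
#'
#' Conjugate-Gaussian update of a zero-mean prior with a single noisy
#' measurement. The posterior mean is `weight * m` for measurement `m`, where
#' the shrinkage weight is `sigma2_prior / (sigma2_prior + sigma2_like)`, and
#' the posterior variance is `weight * sigma2_like`. Noisier measurements are
#' pulled harder towards the stationary (zero) prior mean.
#'
#' @param sigma2_prior prior variance (> 0), mm^2/s^2.
#' @param sigma2_like likelihood (measurement-noise) variance (> 0), mm^2/s^2.
#' @return An object of class `channel_posterior`: list with elements `weight`
#'   (in (0, 1)) and `post_var` (posterior variance, mm^2/s^2).
#' @export
#' @examples
#' shrinkage_weight(1, 1)        # weight 0.5
#' shrinkage_weight(0.4753, 34)  # heavy shrinkage of a noisy channel
shrinkage_weight <- function(sigma2_prior, sigma2_like) {
  if (any(!is.finite(sigma2_prior)) || any(sigma2_prior <= 0) ||
      any(!is.finite(sigma2_like)) || any(sigma2_like <= 0)) {
    stop("variances must be finite and strictly positive")
  }
  w <- sigma2_prior / (sigma2_prior + sigma2_like)
  structure(list(weight = w, post_var = w * sigma2_like),
            class = "channel_posterior")
}

#' Fused (summed) estimate of world-centred surface velocity
#'
#' The observer's surface-velocity estimate is the sum of one posterior sample
#' from the initial-velocity (proprioceptive) channel and one from the
#' velocity-change (tactile) channel. Because a posterior sample carries both
#' the propagated measurement noise (`w^2 * sigma2`) and the posterior sampling
#' variance (`w * sigma2`), the fused estimate is Gaussian with
#'
#'   mean = w_p * v_prop + w_t * (v_surf - v_prop)
#'   var  = w_p^2 s_p^2 + w_t^2 s_t^2 + tau_p^2 + tau_t^2
#'
#' When the finger is stationary (`proprioception_active = FALSE`, the control
#' task) the proprioceptive channel is discarded entirely and the tactile slip
#' equals the surface velocity.
#'
#' @param params an [observer_params()] object.
#' @param v_surf world-frame surface velocity (mm/s); may be a vector.
#' @param v_prop pursuit (finger) velocity sensed by proprioception (mm/s);
#'   defaults to `params$v_pursuit`.
#' @param proprioception_active logical; `FALSE` in the stationary-finger
#'   control task. A moving-finger geometry with `v_prop = 0` is routed to the
#'   control formulation.
#' @param low_amplitude logical; if `TRUE` the tactile likelihood variance is
#'   inflated by `kappa_low_amp`.
#' @return An object of class `fused_estimate`: list with vectors `mean` and
#'   `sd` (mm/s) and the channel weights used.
#' @export
fused_distribution <- function(params, v_surf, v_prop = params$v_pursuit,
                               proprioception_active = TRUE,
                               low_amplitude = FALSE) {
  stopifnot(inherits(params, "observer_params"))
  if (!all(is.finite(v_surf))) stop("v_surf must be finite")
  if (proprioception_active && isTRUE(all(v_prop == 0))) {
    proprioception_active <- FALSE  # degenerate pursuit = stationary finger
  }
  s2t <- tact_variance(params, low_amplitude)
  ch_t <- shrinkage_weight(params$sigma2_prior_tact, s2t)
  if (proprioception_active) {
    if (!is.finite(v_prop)) stop("v_prop must be finite")
    ch_p <- shrinkage_weight(params$sigma2_prior_prop, params$sigma2_prop)
    dv <- v_surf - v_prop
    m <- ch_p$weight * v_prop + ch_t$weight * dv
    v <- ch_p$weight^2 * params$sigma2_prop + ch_t$weight^2 * s2t +
      ch_p$post_var + ch_t$post_var
    w_p <- ch_p$weight
  } else {
    m <- ch_t$weight * v_surf
    v <- ch_t$weight^2 * s2t + ch_t$post_var
    w_p <- 0
  }
  structure(list(mean = m, sd = sqrt(v), w_prop = w_p, w_tact = ch_t$weight),
            class = "fused_estimate")
}

#' Probability of an "away" response
#'
#' Probability that the fused surface-velocity estimate exceeds zero, i.e. that
#' the observer reports the surface as moving away from the body. Equals
#' `pnorm(mean / sd)` of the fused distribution and is strictly increasing in
#' `v_surf`.
#'
#' @inheritParams fused_distribution
#' @return Vector of probabilities, one per element of `v_surf`.
#' @export
response_probability <- function(params, v_surf, v_prop = params$v_pursuit,
                                 proprioception_active = TRUE,
                                 low_amplitude = FALSE) {
  fe <- fused_distribution(params, v_surf, v_prop, proprioception_active,
                           low_amplitude)
  stats::pnorm(fe$mean / fe$sd)
}

#' Model-predicted psychometric function for a task condition
#'
#' Closed-form probit intercept and slope of the predicted psychometric
#' function `P(away) = pnorm(intercept + slope * v_surf)`, with the derived
#' point of subjective equality (PSE) and just-noticeable difference (JND).
#' In the main (pursuit) task `PSE = v_pursuit * (1 - w_p / w_t)`: the illusion
#' vanishes when the two channels are equally weighted and grows with the
#' weight asymmetry. In the control task the prediction is structurally
#' unbiased (PSE = 0) for any parameter values.
#'
#' @inheritParams fused_distribution
#' @param condition `"main"` (pursuit; proprioception active at
#'   `params$v_pursuit`) or `"control"` (stationary finger).
#' @return An object of class `psychometric_params`: list with `intercept`
#'   (probit units), `slope` (probit units per mm/s), `pse` (mm/s), `jnd`
#'   (mm/s) and `condition`.
#' @export
#' @examples
#' predicted_psychometric(observer_params(), "main")     # biased: the illusion
#' predicted_psychometric(observer_params(), "control")  # PSE exactly 0
predicted_psychometric <- function(params, condition = c("main", "control"),
                                   low_amplitude = FALSE) {
  condition <- match.arg(condition)
  active <- condition == "main" && params$v_pursuit != 0
  fe <- fused_distribution(params, v_surf = 0,
                           v_prop = if (active) params$v_pursuit else 0,
                           proprioception_active = active,
                           low_amplitude = low_amplitude)
  slope <- fe$w_tact / fe$sd
  if (active) {
    intercept <- (fe$w_prop - fe$w_tact) * params$v_pursuit / fe$sd
    pse <- params$v_pursuit * (1 - fe$w_prop / fe$w_tact)
  } else {
    intercept <- 0
    pse <- 0
  }
  structure(list(intercept = intercept, slope = slope, pse = pse,
                 jnd = jnd_from_slope(slope), condition = condition),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "Predicted psychometric (%s): intercept %.4g, slope %.4g /(mm/s), PSE %.4g mm/s, JND %.4g mm/s\n",
    x$condition, x$intercept, x$slope, x$pse, x$jnd))
  invisible(x)
}

#' Predicted probit slope in a unimodal discrimination task
#'
#' Slope of the psychometric function of an observer who judges velocity from
#' a single sensory channel (the other channel discarded), with the channel's
#' measurement combined with the stationarity prior. With shrinkage weight `w`
#' and likelihood variance `sigma2`, the slope is
#' `w / sqrt(w^2 sigma2 + w sigma2) = sqrt(w / (sigma2 (1 + w)))`, decreasing
#' in the likelihood variance.
#'
#' @inheritParams shrinkage_weight
#' @return Probit slope in units of 1/(mm/s).
#' @export
predicted_unimodal_slope <- function(sigma2_prior, sigma2_like) {
  ch <- shrinkage_weight(sigma2_prior, sigma2_like)
  ch$weight / sqrt(ch$weight^2 * sigma2_like + ch$post_var)
}

#' Calibrate the prior variance from a target unimodal slope
#'
#' Inverts [predicted_unimodal_slope()]: returns the unique prior variance at
#' which the predicted unimodal probit slope equals `slope_target` for a
#' channel with likelihood variance `sigma2_like`. Closed form: with
#' `s = slope_target`, `w = s^2 sigma2 / (1 - s^2 sigma2)` and
#' `sigma2_prior = w sigma2 / (1 - w)`. The attainable range is
#' `0 < s < 1 / sqrt(2 sigma2_like)` (the supremum as the prior variance grows
#' without bound); targets at or beyond the bound are rejected.
#'
#' @param slope_target probit slope, 1/(mm/s).
#' @param sigma2_like likelihood variance (mm^2/s^2).
#' @return Prior variance (mm^2/s^2).
#' @export
#' @examples
#' calibrate_prior_variance(0.02, 34)  # ~0.4753
calibrate_prior_variance <- function(slope_target, sigma2_like) {
  if (!is.finite(sigma2_like) || sigma2_like <= 0) {
    stop("sigma2_like must be finite and > 0")
  }
  upper <- 1 / sqrt(2 * sigma2_like)
  if (!is.finite(slope_target) || slope_target <= 0 || slope_target >= upper) {
    stop(sprintf(
      "slope_target must lie in (0, %.6g) for sigma2_like = %.6g",
      upper, sigma2_like))
  }
  s2 <- slope_target^2 * sigma2_like
  w <- s2 / (1 - s2)
  w * sigma2_like / (1 - w)
}

#' Just-noticeable difference from a probit slope
#'
#' Velocity increment that moves the response probability from 0.5 to 0.75:
#' `qnorm(0.75) / slope`.
#'
#' @param slope probit slope (> 0), 1/(mm/s).
#' @return JND in mm/s.
#' @export
#' @examples
#' jnd_from_slope(0.02)  # ~33.7 mm/s
#' jnd_from_slope(0.06)  # ~11.2 mm/s
jnd_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope <= 0)) stop("slope must be > 0")
  stats::qnorm(0.75) / slope
}

#' Haptic Filehne gain
#'
#' Quantifies how completely finger motion is taken into account when judging
#' surface motion: `1 - pse_main / v_pursuit_mean`. A gain of 1 means veridical
#' compensation (no illusion, PSE 0); a gain of 0 means the pursuit velocity is
#' ignored entirely (PSE equal to the finger speed).
#'
#' @param pse_main point of subjective equality in the pursuit task (mm/s).
#' @param v_pursuit_mean mean finger velocity (mm/s); must be nonzero.
#' @return Dimensionless gain.
#' @export
#' @examples
#' filehne_gain(6.8, 10.8)  # ~0.37, i.e. ~0.4
filehne_gain <- function(pse_main, v_pursuit_mean) {
  if (!is.finite(v_pursuit_mean) || v_pursuit_mean == 0) {
    stop("v_pursuit_mean must be nonzero")
  }
  1 - pse_main / v_pursuit_mean
}

#' Perceived surface velocity with an incomplete pursuit gain
#'
#' Biased velocity summation `v_tact + gain * v_prop`. With `gain = 1` this is
#' the ideal (veridical) summation of slip and finger velocity; with a gain
#' below 1 a world-stationary surface (`v_tact = -v_prop`) is perceived as
#' moving opposite to the hand at speed `(1 - gain) * v_prop`.
#'
#' @param v_tact tactile slip velocity (mm/s).
#' @param v_prop finger velocity (mm/s).
#' @param gain dimensionless compensation gain.
#' @return Perceived surface velocity (mm/s).
#' @export
perceived_velocity_biased <- function(v_tact, v_prop, gain) {
  v_tact + gain * v_prop
}
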