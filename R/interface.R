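trial_columns <- c("observer_id", "experiment", "condition", "v_surf",
                   "v_prop", "amplitude", "response")

#' Write trial records to the canonical CSV
#'
#' @param trials trial records containing at least the canonical columns
#'   (`observer_id`, `experiment`, `condition`, `v_surf`, `v_prop`,
#'   `amplitude`, `response`); extra columns (e.g. `v_std`) are preserved.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss)) {
    stop("trials is missing columns: ", paste(miss, collapse = ", "))
  }
  ord <- c(trial_columns, setdiff(names(trials), trial_columns))
  utils::write.csv(trials[, ord], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate trial records from CSV
#'
#' Strictly validates the canonical schema: all canonical columns present,
#' responses binary, velocities finite, amplitudes positive. Malformed rows
#' are reported by row index.
#'
#' @param path CSV path written by [write_trials()] (or of the same schema).
#' @return data.frame of trial records.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss)) {
    stop("trial file is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!(trials$response %in% c(0L, 1L)))
  if (length(bad)) {
    stop("non-binary response at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  for (col in c("v_surf", "v_prop")) {
    bad <- which(!is.finite(trials[[col]]))
    if (length(bad)) {
      stop("non-finite ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  bad <- which(!is.finite(trials$amplitude) | trials$amplitude <= 0)
  if (length(bad)) {
    stop("invalid amplitude at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  trials
}

#' Configuration of an end-to-end synthetic run
#'
#' A run is fully reproducible from its configuration and seed: the config
#' fixes the experiment design, the generative population, the fitting options
#' and the bootstrap sizes.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_observers simulated observers.
#' @param population optional [population_spec()]; built from defaults (exp1)
#'   or from the generative observer model (exp2) when `NULL`.
#' @param observer optional [observer_params()] generative observer (used for
#'   exp3 simulation and as reference); defaults to [observer_params()].
#' @param sigma2_prior prior-variance constraint of the observer-model fit.
#' @param n_starts optimiser starts for the observer-model fit.
#' @param hierarchical_reps bootstrap replicates for the hierarchical PSE CIs
#'   (0 disables this stage; a full analysis uses 1000).
#' @param bayes_reps replicates of the observer-model parametric bootstrap
#'   (0 disables; a full analysis uses 1000).
#' @param seed master integer seed.
#' @param out_dir optional directory; when set, trials, tidy results and a
#'   JSON report are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = "exp1", n_observers = 10,
                       population = NULL, observer = observer_params(),
                       sigma2_prior = 0.4753, n_starts = 5,
                       hierarchical_reps = 0, bayes_reps = 200,
                       seed = 1L, out_dir = NULL) {
  if (!experiment %in% c("exp1", "exp2", "exp3")) {
    stop("unknown experiment: ", experiment)
  }
  structure(list(experiment = experiment, n_observers = n_observers,
                 population = population, observer = observer,
                 sigma2_prior = sigma2_prior, n_starts = n_starts,
                 hierarchical_reps = hierarchical_reps,
                 bayes_reps = bayes_reps, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# condition-specific fixed effects implied by a generative observer
observer_fixed_effects <- function(observer, experiment) {
  if (experiment == "exp2") {
    hi <- predicted_psychometric(observer, "main", low_amplitude = FALSE)
    lo <- predicted_psychometric(observer, "main", low_amplitude = TRUE)
    data.frame(condition = c("high_amp", "low_amp"),
               intercept = c(hi$intercept, lo$intercept),
               slope = c(hi$slope, lo$slope))
  } else {
    mn <- predicted_psychometric(observer, "main")
    ct <- predicted_psychometric(observer, "control")
    data.frame(condition = c("main", "control"),
               intercept = c(mn$intercept, ct$intercept),
               slope = c(mn$slope, ct$slope))
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate (design + heterogeneous population) -> per-observer probit fits
#' and QC flags -> hierarchical probit fit (-> optional PSE bootstrap) ->
#' observer-model fit and parametric bootstrap (exp1) or slope LRT (exp2) or
#' discrimination JNDs (exp3) -> summary quantities (PSE, gain, JND). Every
#' source of randomness derives from `config$seed`; the same config yields an
#' identical report.
#'
#' @param config a [run_config()].
#' @return A report list with the config echo, seeds, design counts, all fit
#'   summaries and the derived quantities.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  exp <- config$experiment

  design <- run_stage("design", make_design(exp, seed = seed))

  trials <- run_stage("simulate", {
    if (exp == "exp3") {
      do.call(rbind, lapply(seq_len(config$n_observers), function(i) {
        simulate_observer_responses(config$observer, design,
                                    seed = seed + 100L + i,
                                    observer_id = sprintf("obs%02d", i))
      }))
    } else {
      spec <- config$population
      if (is.null(spec)) {
        fe <- if (exp == "exp1") {
          population_spec(config$n_observers)$fixed_effects
        } else {
          observer_fixed_effects(config$observer, exp)
        }
        spec <- population_spec(config$n_observers, fixed_effects = fe)
      }
      trials <- simulate_population(spec, design, seed = seed + 1L)
      trials$experiment <- exp
      trials
    }
  })

  qc <- run_stage("qc", qc_trials(trials))

  observer_fits <- run_stage("observer_fits", {
    cells <- unique(trials[, c("observer_id", "condition")])
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- trials[trials$observer_id == cells$observer_id[i] &
                      trials$condition == cells$condition[i], ]
      fit <- tryCatch(fit_probit_ml(sub), error = function(e) NULL)
      data.frame(observer_id = cells$observer_id[i],
                 condition = cells$condition[i],
                 intercept = if (is.null(fit)) NA else fit$coefficients[1],
                 slope = if (is.null(fit)) NA else fit$coefficients[2],
                 pse = if (is.null(fit)) NA else fit$pse,
                 jnd = if (is.null(fit)) NA else fit$jnd)
    }))
  })

  report <- list(
    package_version = as.character(utils::packageVersion("filehne")),
    config = unclass(config[c("experiment", "n_observers", "sigma2_prior",
                              "n_starts", "hierarchical_reps", "bayes_reps",
                              "seed")]),
    design = list(n_trials = nrow(design),
                  conditions = table(design$condition)),
    qc = qc,
    observer_fits = observer_fits)

  if (exp == "exp3") {
    report$discrimination <- run_stage("discrimination", {
      lapply(split(trials, trials$condition), function(sub) {
        fit <- fit_discrimination(sub)
        list(jnd = fit$jnd, jnd_se = fit$jnd_se, slope = fit$coefficients[2])
      })
    })
    return(write_outputs(report, trials, config))
  }

  hier <- run_stage("hierarchical_fit", fit_hierarchical_probit(trials))
  report$hierarchical <- list(fixed = hier$fixed, re_cov = hier$re_cov,
                              loglik = hier$loglik,
                              singular = hier$diagnostics$singular)

  if (config$hierarchical_reps > 0) {
    report$pse_bootstrap <- run_stage("pse_bootstrap", {
      b <- bootstrap_pse_ci(hier, n_reps = config$hierarchical_reps,
                            seed = seed + 2L)
      list(point = b$point, ci = b$ci, n_failed = b$n_failed)
    })
  }

  if (exp == "exp2") {
    report$slope_lrt <- run_stage("slope_lrt", {
      reduced <- fit_hierarchical_probit(trials, common_slope = TRUE)
      lrt_slopes(hier, reduced)
    })
  } else {
    fx <- hier$fixed
    pse_main <- fx$pse[fx$condition == "main"]
    pse_ctrl <- fx$pse[fx$condition == "control"]
    vbar <- mean(trials$v_prop[trials$condition == "main"])
    report$gain <- run_stage("gain", filehne_gain(pse_main, vbar))

    report$bayes <- run_stage("bayes_fit", {
      fit <- fit_observer_model(trials, sigma2_prior = config$sigma2_prior,
                                n_starts = config$n_starts)
      out <- list(sigma2_prop = fit$sigma2_prop,
                  sigma2_tact = fit$sigma2_tact, ratio = fit$ratio,
                  pse_main_pred = fit$predicted$main$pse,
                  pse_control_pred = fit$predicted$control$pse,
                  loglik = fit$loglik)
      if (config$bayes_reps > 0) {
        # the published scheme: control forced unbiased, main at its PSE
        b_main <- c(-pse_main * fx$slope[fx$condition == "main"],
                    fx$slope[fx$condition == "main"])
        b_ctrl <- c(0, fx$slope[fx$condition == "control"])
        boot <- parametric_bootstrap_fit(
          b_main, b_ctrl, n_reps = config$bayes_reps, seed = seed + 3L,
          sigma2_prior = config$sigma2_prior, v_pursuit = vbar)
        out$bootstrap <- list(point = boot$point, ci = boot$ci,
                              n_failed = boot$n_failed)
      }
      out
    })
    report$summary <- data.frame(
      quantity = c("pse_main", "pse_control", "gain", "pse_main_bayes"),
      value = c(pse_main, pse_ctrl, report$gain,
                report$bayes$pse_main_pred))
  }
  write_outputs(report, trials, config)
}

write_outputs <- function(report, trials, config) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    utils::write.csv(report$observer_fits,
                     file.path(config$out_dir, "observer_fits.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(report,
                           file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  report
}
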