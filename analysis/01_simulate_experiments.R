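#!/usr/bin/env Rscript
# Generate the three synthetic experiments used throughout the analysis:
#   exp1 - direction judgements during pursuit vs stationary finger
#          (10 observers x 195 trials; heterogeneous population with group
#           PSEs 6.8 / -1.6 mm/s)
#   exp2 - pursuit with high/low pin-oscillation amplitude intermixed
#          (10 observers x 200 trials; generative observer with the tactile
#           variance doubled at low amplitude)
#   exp3 - two-interval speed discrimination with a stationary hand
#          (8 observers x 192 trials)
# Writes canonical trial CSVs under results/.

suppressPackageStartupMessages(library(filehne))
dir.create("results", showWarnings = FALSE)
seed <- 20150928L

## exp1: hierarchical population generator
d1 <- make_design("exp1", seed = seed)
tr1 <- simulate_population(population_spec(10), d1, seed = seed + 1)
tr1$experiment <- "exp1"
write_trials(tr1, "results/trials_exp1.csv")

## exp2: forward-simulated from the calibrated Bayesian observer
obs <- observer_params(sigma2_prior_prop = calibrate_prior_variance(0.02, 34))
d2 <- make_design("exp2", seed = seed)
tr2 <- do.call(rbind, lapply(1:10, function(i) {
  simulate_observer_responses(obs, d2, seed = seed + 10 + i,
                              observer_id = sprintf("obs%02d", i))
}))
write_trials(tr2, "results/trials_exp2.csv")

## exp3: two-interval discrimination from the same observer
d3 <- make_design("exp3", seed = seed)
tr3 <- do.call(rbind, lapply(1:8, function(i) {
  simulate_observer_responses(obs, d3, seed = seed + 30 + i,
                              observer_id = sprintf("obs%02d", i))
}))
write_trials(tr3, "results/trials_exp3.csv")

cat(sprintf("exp1: %d trials, %d observers\n", nrow(tr1),
            length(unique(tr1$observer_id))))
cat(sprintf("exp2: %d trials, %d observers\n", nrow(tr2),
            length(unique(tr2$observer_id))))
cat(sprintf("exp3: %d trials, %d observers\n", nrow(tr3),
            length(unique(tr3$observer_id))))
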