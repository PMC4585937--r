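#!/usr/bin/env Rscript
# Fit the stationarity-prior observer model to the exp1 trials by constrained
# maximum likelihood, then run the parametric-bootstrap population procedure:
# simulate binomial sessions from the descriptive psychometric functions
# (control forced unbiased, main at its estimated PSE), refit the observer
# model to each, and summarise the recovered variances and predicted PSE.

suppressPackageStartupMessages(library(filehne))
trials <- read_trials("results/trials_exp1.csv")

hier <- fit_hierarchical_probit(trials)
fx <- hier$fixed
pse_main <- fx$pse[fx$condition == "main"]
slope_main <- fx$slope[fx$condition == "main"]
slope_ctrl <- fx$slope[fx$condition == "control"]
vbar <- mean(trials$v_prop[trials$condition == "main"])

fit <- fit_observer_model(trials)
print(fit)

boot <- parametric_bootstrap_fit(
  b_main = c(-pse_main * slope_main, slope_main),
  b_control = c(0, slope_ctrl),
  n_reps = 200, seed = 4L, v_pursuit = vbar)
print(boot)

gain <- filehne_gain(pse_main, vbar)
cat(sprintf("haptic Filehne gain: 1 - %.1f/%.1f = %.2f\n",
            pse_main, vbar, gain))

write.csv(rbind(
  data.frame(quantity = c("sigma2_prop", "sigma2_tact", "ratio",
                          "pse_main_model", "gain"),
             estimate = c(fit$sigma2_prop, fit$sigma2_tact, fit$ratio,
                          fit$predicted$main$pse, gain)),
  data.frame(quantity = paste0("boot_", boot$ci$quantity),
             estimate = boot$point[boot$ci$quantity])),
  "results/exp1_bayes_fit.csv", row.names = FALSE)
cat("wrote results/exp1_bayes_fit.csv\n")
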