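#!/usr/bin/env Rscript
# The model's diagnostic prediction: more tactile noise, smaller illusion.
# exp2: hierarchical fit of the high/low-amplitude pursuit sessions, the
# likelihood-ratio test on the slopes (is the low-amplitude response
# noisier?), and the PSE shift. exp3: two-interval discrimination JNDs
# confirming that oscillation amplitude modulates tactile precision.

suppressPackageStartupMessages(library(filehne))

## exp2 ---------------------------------------------------------------
trials2 <- read_trials("results/trials_exp2.csv")
hier <- fit_hierarchical_probit(trials2)
reduced <- fit_hierarchical_probit(trials2, common_slope = TRUE)
lrt <- lrt_slopes(hier, reduced)
print(hier)
cat(sprintf("slope LRT: chi2(%d) = %.2f, p = %.3g%s\n", lrt$df,
            lrt$statistic, lrt$p_value,
            if (lrt$p_value < 0.05) " -- low amplitude is noisier" else ""))

boot <- bootstrap_pse_ci(hier, n_reps = 100, seed = 3L)
dci <- pse_difference_ci(boot, "high_amp", "low_amp")
cat(sprintf("PSE_high - PSE_low: %.2f mm/s, 95%% CI [%.2f, %.2f]\n",
            dci$estimate, dci$lower, dci$upper))

fx <- hier$fixed
write.csv(data.frame(quantity = c(paste0("pse_", fx$condition),
                                  "pse_difference", "lrt_p"),
                     estimate = c(fx$pse, dci$estimate, lrt$p_value)),
          "results/exp2_amplitude_effect.csv", row.names = FALSE)

## exp3 ---------------------------------------------------------------
trials3 <- read_trials("results/trials_exp3.csv")
jnds <- lapply(split(trials3, trials3$condition), function(sub) {
  fit <- fit_discrimination(sub)
  c(jnd = fit$jnd, se = fit$jnd_se)
})
cat(sprintf("discrimination JND: high %.1f +/- %.1f mm/s, low %.1f +/- %.1f mm/s\n",
            jnds$high_amp["jnd"], jnds$high_amp["se"],
            jnds$low_amp["jnd"], jnds$low_amp["se"]))
write.csv(data.frame(condition = names(jnds),
                     jnd = sapply(jnds, `[`, "jnd"),
                     se = sapply(jnds, `[`, "se")),
          "results/exp3_discrimination.csv", row.names = FALSE)
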