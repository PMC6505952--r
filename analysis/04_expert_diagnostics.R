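#!/usr/bin/env Rscript
# Stage 4 — per-expert diagnostics on the scenario with a BAU future: mean
# AL vs mean MG per expert and attribute, opinion-quadrant classification,
# the AL-MG linear relationship (a negative slope means experts pessimistic
# about the counterfactual also expect less from the offset), and flags for
# systematically optimistic or pessimistic experts.

library(offsetElicit)

samples <- read.csv("results/benefit_samples.csv")
with_bau <- samples[!is.na(samples$AL), ]

means <- expert_means(with_bau)
means$quadrant <- classify_quadrant(means$mean_AL, means$mean_MG)
write.csv(means, "results/expert_diagnostics.csv", row.names = FALSE)

cat("opinion quadrants across expert x attribute means:\n")
print(table(means$quadrant))

fits_tab <- do.call(rbind, lapply(sort(unique(means$attribute)), function(a) {
  f <- al_mg_fit(means, a)
  data.frame(attribute = a, slope = f$slope, correlation = f$correlation,
             n_experts = f$n)
}))
write.csv(fits_tab, "results/al_mg_fits.csv", row.names = FALSE)
cat(sprintf("\nAL-MG slopes negative for %d of %d attributes (median r = %.2f)\n",
            sum(fits_tab$slope < 0), nrow(fits_tab),
            median(fits_tab$correlation)))

flags <- systematic_bias(means)
write.csv(flags, "results/expert_bias_flags.csv", row.names = FALSE)
cat("\nsystematic-bias flags:\n")
print(table(flags$bias, useNA = "ifany"))
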