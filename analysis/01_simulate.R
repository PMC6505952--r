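#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# The elicitation data behind this kind of study are rarely deposited, so the
# analysis runs on a synthetic panel with known ground truth: 64 sites on a
# condition gradient, 29 point-score experts (15 sites each, 5 common, 16
# also scoring a BAU future) and 25 roulette experts covering the three
# grassy-woodland scenarios. Everything downstream reads the CSVs written
# here.

library(offsetElicit)

seed <- 101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- generator_config()

sites <- simulate_site_pool(cfg, seed = seed)
write_sites(sites, file.path(out, "sites.csv"))
write.csv(sites[, c("site_id", "latent_u", "true_score")],
          file.path(out, "ground_truth_sites.csv"), row.names = FALSE)

ps <- simulate_point_scores(sites, cfg, seed = seed + 1)
write_point_scores(ps$scores, file.path(out, "point_scores.csv"))
write.csv(ps$truth, file.path(out, "ground_truth_benefit.csv"), row.names = FALSE)
write.csv(ps$experts, file.path(out, "ground_truth_experts.csv"), row.names = FALSE)

scenarios <- wsgw_scenarios()
elic <- list(); truth <- list()
for (i in seq_along(scenarios)) {
  sim <- simulate_roulette_elicitations(scenarios[[i]], cfg, seed = seed + 1 + i)
  elic[[i]] <- sim$elicitations
  truth[[i]] <- sim$truth
}
elic <- do.call(rbind, elic)
write_elicitations(elic, file.path(out, "elicitations.csv"))
write.csv(do.call(rbind, truth), file.path(out, "ground_truth_roulette.csv"),
          row.names = FALSE)

cat(sprintf("sites: %d (true score %.0f-%.0f)\n", nrow(sites),
            min(sites$true_score), max(sites$true_score)))
cat(sprintf("point scores: %d rows from %d experts (%d with BAU futures)\n",
            nrow(ps$scores), length(unique(ps$scores$expert_id)),
            length(unique(ps$scores$expert_id[!is.na(ps$scores$future_bau)]))))
cat(sprintf("roulette records: %d over %d scenarios\n", nrow(elic),
            length(scenarios)))
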