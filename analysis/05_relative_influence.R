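#!/usr/bin/env Rscript
# Stage 5 — boosted-regression-tree analysis of the point scores: which
# covariates (13 vegetation attributes, landscape cover, alien covers,
# expert identity, and for change responses the expert's current score)
# carry the variation in current condition, MG, AL and TB? Reported as
# normalised relative influence (sums to 100); plus partial-dependence
# curves for the leading covariates and ensemble condition predictions for
# the three elicitation scenarios.

library(offsetElicit)

scores <- read_point_scores("results/data/point_scores.csv")
sites <- read_sites("results/data/sites.csv")
cfg <- brt_config(tree_complexity = 5, learning_rate = 0.005,
                  bag_fraction = 0.75, cv_folds = 10, tree_step = 50,
                  max_trees = 4000)

influence <- list(); pd <- list(); fits <- list()
for (resp in c("current", "MG", "AL", "TB")) {
  cfg$seed <- 500 + match(resp, c("current", "MG", "AL", "TB"))
  design <- build_design(scores, sites, response = resp)
  fit <- fit_brt(design, cfg)
  fits[[resp]] <- fit
  ri <- relative_influence(fit)
  cat(sprintf("\n%s (%d rows, %d trees): top influences\n", resp,
              length(design$y), fit$n_trees))
  print(head(ri, 5), row.names = FALSE, digits = 3)
  influence[[resp]] <- cbind(response = resp, ri)
  for (cv in head(ri$covariate[ri$covariate != "expert_id"], 3)) {
    curve <- fitted_function(fit, cv)
    pd[[paste(resp, cv)]] <- cbind(response = resp, covariate = cv, curve)
  }
}
write.csv(do.call(rbind, influence), "results/influence.csv", row.names = FALSE)
write.csv(do.call(rbind, pd), "results/partial_dependence.csv", row.names = FALSE)

# ensemble condition predictions for the three scenario descriptions
scen_sites <- do.call(rbind, lapply(wsgw_scenarios(), function(sc) {
  row <- as.data.frame(as.list(sc$start_values))
  row$site_id <- sc$id
  row$landscape_cover <- sc$landscape_cover_pct
  row$invasive_alien_cover <- sc$invasive_alien_cover_pct
  row$total_alien_cover <- sc$total_alien_cover_pct
  row
}))
members <- lapply(c(601, 602, 603), function(s) {
  cfg$seed <- s
  fit_brt(build_design(scores, sites, "current"), cfg)
})
pred <- predict_condition(members, scen_sites)
write.csv(pred, "results/predictions.csv", row.names = FALSE)
cat("\nensemble condition predictions for the elicitation scenarios:\n")
print(pred, row.names = FALSE, digits = 3)
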