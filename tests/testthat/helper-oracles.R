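# Independent oracles and small fixture builders used across the test files.
# Everything here reimplements the quantity it checks from first principles,
# without calling the code path under test.

# CDF-matching objective, written out independently of the package's fitter.
oracle_sse_normal <- function(mu, sigma, edges, cum_probs) {
  sum((pnorm(edges, mu, sigma) - cum_probs)^2)
}
oracle_sse_beta <- function(alpha, beta, edges01, cum_probs) {
  sum((pbeta(edges01, alpha, beta) - cum_probs)^2)
}

# Exhaustive grid search minimising the same objective: the independent
# oracle for the distribution-fit recovery checks.
oracle_grid_normal <- function(edges, cum_probs, mu_grid, sd_grid) {
  grid <- expand.grid(mu = mu_grid, sd = sd_grid)
  sse <- mapply(function(m, s) oracle_sse_normal(m, s, edges, cum_probs),
                grid$mu, grid$sd)
  c(mu = grid$mu[which.min(sse)], sd = grid$sd[which.min(sse)],
    sse = min(sse))
}
oracle_grid_beta <- function(edges01, cum_probs, a_grid, b_grid) {
  grid <- expand.grid(a = a_grid, b = b_grid)
  sse <- mapply(function(a, b) oracle_sse_beta(a, b, edges01, cum_probs),
                grid$a, grid$b)
  c(alpha = grid$a[which.min(sse)], beta = grid$b[which.min(sse)],
    sse = min(sse))
}

# Discretise a known distribution onto 10 bins over [tmin, tmax] as integer
# chips summing to 100 (simple floor-and-top-up allocator, local to the tests).
chips_from_cdf <- function(cdf, tmin, tmax) {
  edges <- seq(tmin, tmax, length.out = 11)
  mass <- diff(cdf(edges))
  mass <- mass / sum(mass)
  raw <- mass * 100
  chips <- floor(raw)
  left <- 100 - sum(chips)
  ord <- order(raw - chips, decreasing = TRUE)
  if (left > 0) chips[ord[seq_len(left)]] <- chips[ord[seq_len(left)]] + 1
  as.integer(chips)
}

# One row in the fit_elicitations() output schema, built directly.
fit_row <- function(expert, attribute, state, family, p1, p2,
                    scenario = "sc") {
  data.frame(expert_id = expert, scenario_id = scenario,
             attribute = attribute, state = state, family = family,
             param1 = p1, param2 = p2, fit_sse = 0, single_bin = FALSE,
             multimodal = FALSE, stringsAsFactors = FALSE)
}

# Benefit-sample rows built directly (for summariser/diagnostics tests).
sample_rows <- function(expert, attribute, AL, MG, BC_start = 0.5) {
  n <- max(length(AL), length(MG))
  AL <- rep_len(AL, n); MG <- rep_len(MG, n)
  data.frame(expert_id = expert, attribute = attribute, draw = seq_len(n),
             BC_start = BC_start, BC_bau = BC_start - AL,
             BC_offset = BC_start + MG, AL = AL, MG = MG, TB = AL + MG,
             stringsAsFactors = FALSE)
}

# A small but complete roulette panel for one scenario: returns the
# elicitation table plus generator truth.
small_panel <- function(seed, n_experts = 6, attrs = c("grass_cover",
                        "forb_richness", "log_length"),
                        states = c("reference", "future_bau", "future_offset"),
                        config = generator_config(), scenario_u = 0.60) {
  atts <- wsgw_attributes()
  atts <- atts[atts$name %in% attrs, , drop = FALSE]
  config$n_experts_roulette <- n_experts
  sc <- wsgw_scenarios()[[1]]
  if (scenario_u != sc$u) {
    sc$u <- scenario_u
    sc$start_values <- scenario_start_values(scenario_u)
  }
  sc$states_elicited <- states
  sim <- simulate_roulette_elicitations(sc, config, seed = seed,
                                        attributes = atts)
  list(elicitations = sim$elicitations, truth = sim$truth, scenario = sc,
       attributes = atts)
}

# A purely numeric model table wrapped as a brt_design (no expert factor).
num_design <- function(x, y, response = "current") {
  structure(list(x = x, y = y, response = response, covariates = names(x)),
            class = "brt_design")
}

# Small boosting configuration for test-sized problems.
fast_brt <- function(seed = 1, ...) {
  brt_config(learning_rate = 0.05, max_trees = 400, tree_step = 25,
             cv_folds = 5, seed = seed, ...)
}
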