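#' @title Synthetic site pools and expert panels with known ground truth
#' @description
#' The study's elicitation data are not deposited, so every downstream stage
#' is exercised against synthetic data whose generating process is known.
#' The generator emulates the statistical structure the analysis assumes:
#' 64 sites spanning a latent condition gradient; a panel of 29 experts each
#' scoring 15 sites (5 common to all) with expert-level intercepts
#' (consistently generous or harsh scorers) and scoring noise; and a panel
#' of 25 experts providing roulette histograms for reference and future
#' states, with a shared per-expert "temporal optimism" term that shifts
#' BAU and offset futures jointly (inducing the negative AL-MG association
#' across experts) and an overconfidence factor that shrinks subjective
#' spread. True management gain declines linearly with starting condition:
#' MG* = a (1 - BC_start) + b on the condition scale.
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults mirror the study design (64 sites, 29 point-score experts of
#' whom 16 also scored a BAU future, 25 roulette experts, 15 sites per
#' expert with 5 common) with effect sizes a field scientist would call
#' realistic for this kind of panel: expert intercepts of sd 8 points and
#' scoring noise of sd 5 points on the 0-100 scale, true management gain
#' 0.125 (1 - BC_start) and true averted loss 0.08 BC_start + 0.01 on the
#' condition scale (placing typical gains and losses at a handful of points
#' per 100), expert bias sd 0.05 condition units, and an overconfidence
#' factor of 0.8.
#'
#' `oracle_mode = TRUE` zeroes every noise, bias and change term and makes
#' subjective distributions effectively point masses, so each downstream
#' operation has an exact expected output.
#'
#' @param n_sites,n_experts_points,n_experts_bau,n_experts_roulette Panel sizes.
#' @param sites_per_expert,n_common Site assignment per point-score expert.
#' @param true_condition_weights Named weights of the attributes in the true
#'   aggregate score (`NULL` = equal).
#' @param expert_intercept_sd,expert_score_noise_sd Points on 0-100.
#' @param true_mg,true_al Parameters `c(a, b)` of MG* = a(1 - BC) + b and
#'   AL* = a BC + b on the condition scale.
#' @param bias_sd Sd of the per-expert temporal-optimism term (condition units).
#' @param overconfidence_factor Multiplier in (0, 1\] shrinking subjective sd.
#' @param site_noise_cv Coefficient of variation of site attribute noise.
#' @param sd_scale Extra multiplier on subjective sd (oracle mode sets 1e-9).
#' @param oracle_mode Zero-noise, zero-change degenerate mode.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 64, n_experts_points = 29,
                             n_experts_bau = 16, n_experts_roulette = 25,
                             sites_per_expert = 15, n_common = 5,
                             true_condition_weights = NULL,
                             expert_intercept_sd = 8,
                             expert_score_noise_sd = 5,
                             true_mg = c(a = 0.125, b = 0),
                             true_al = c(a = 0.08, b = 0.01),
                             bias_sd = 0.05,
                             overconfidence_factor = 0.8,
                             site_noise_cv = 0.15,
                             sd_scale = 1,
                             oracle_mode = FALSE) {
  if (oracle_mode) {
    expert_intercept_sd <- 0; expert_score_noise_sd <- 0
    true_mg <- c(a = 0, b = 0); true_al <- c(a = 0, b = 0)
    bias_sd <- 0; site_noise_cv <- 0; sd_scale <- 1e-9
  }
  stopifnot(n_sites >= 1, n_experts_points >= 1,
            n_experts_bau <= n_experts_points, n_experts_roulette >= 1,
            n_common <= sites_per_expert, sites_per_expert <= n_sites,
            overconfidence_factor > 0, overconfidence_factor <= 1)
  structure(list(n_sites = n_sites, n_experts_points = n_experts_points,
                 n_experts_bau = n_experts_bau,
                 n_experts_roulette = n_experts_roulette,
                 sites_per_expert = sites_per_expert, n_common = n_common,
                 true_condition_weights = true_condition_weights,
                 expert_intercept_sd = expert_intercept_sd,
                 expert_score_noise_sd = expert_score_noise_sd,
                 true_mg = true_mg, true_al = true_al, bias_sd = bias_sd,
                 overconfidence_factor = overconfidence_factor,
                 site_noise_cv = site_noise_cv, sd_scale = sd_scale,
                 oracle_mode = oracle_mode),
            class = "generator_config")
}

#' Allocate an integer budget to bins by largest remainder
#'
#' Scales a probability vector to `total`, takes floors, and hands the
#' remaining units to the bins with the largest fractional parts (ties by
#' bin order). The result always sums exactly to `total`.
#'
#' @param p Non-negative weights (need not sum to 1).
#' @param total Integer budget (default 100 chips).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(p, total = 100L) {
  stopifnot(all(p >= 0), sum(p) > 0)
  raw <- p / sum(p) * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  frac <- raw - base
  if (short > 0) {
    idx <- order(-frac, seq_along(p))[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Simulate a pool of sites along a condition gradient
#'
#' Each site has a latent condition `u ~ Uniform(0, 1)`; native attributes
#' are a monotone fraction of their reference mean at `u` with multiplicative
#' noise, alien covers decrease in `u`, and landscape native cover increases
#' in `u`. Values are clipped to supports and counts rounded.
#'
#' @param config A [generator_config()].
#' @param seed Seed.
#' @param attributes,reference Attribute and benchmark tables.
#' @return data.frame in the site schema of [write_sites()], plus columns
#'   `latent_u` and `true_score` (ground truth, dropped by the writer).
#' @export
simulate_site_pool <- function(config = generator_config(), seed = 1,
                               attributes = wsgw_attributes(),
                               reference = wsgw_reference_distributions()) {
  set.seed(seed)
  n <- config$n_sites
  u <- stats::runif(n)
  sites <- data.frame(site_id = sprintf("S%02d", seq_len(n)), latent_u = u,
                      stringsAsFactors = FALSE)
  for (a in seq_len(nrow(attributes))) {
    nm <- attributes$name[a]
    rm_ <- reference$ref_mean[match(nm, reference$name)]
    noise <- if (config$site_noise_cv > 0)
      exp(stats::rnorm(n, 0, config$site_noise_cv)) else 1
    v <- rm_ * (0.05 + 0.95 * u) * noise
    v <- pmin(pmax(v, attributes$support_min[a]), attributes$support_max[a])
    if (attributes$category[a] %in% c("richness_count", "large_tree_count")) {
      v <- round(v)
    }
    sites[[nm]] <- v
  }
  nz <- function(sd_) if (config$site_noise_cv > 0) stats::rnorm(n, 0, sd_) else 0
  sites$landscape_cover <- pmin(pmax(20 + 60 * u + nz(8), 0), 100)
  sites$invasive_alien_cover <- pmin(pmax(55 * (1 - u) - 5 + nz(6), 0), 100)
  sites$total_alien_cover <- pmin(sites$invasive_alien_cover +
                                    pmax(15 * (1 - u) + nz(4), 0), 100)
  sites$true_score <- true_condition_score(sites, config, attributes, reference)
  sites
}

#' True aggregate condition of simulated sites
#'
#' The generator's ground truth: a weighted mean of the capped
#' reference-standardised attribute scores, discounted for invasive alien
#' cover, on 0-100.
#'
#' @param sites Site table.
#' @inheritParams simulate_site_pool
#' @return Numeric vector of true scores.
#' @export
true_condition_score <- function(sites, config = generator_config(),
                                 attributes = wsgw_attributes(),
                                 reference = wsgw_reference_distributions()) {
  w <- config$true_condition_weights
  if (is.null(w)) w <- stats::setNames(rep(1, nrow(attributes)), attributes$name)
  bc <- sapply(names(w), function(nm) {
    condition_score(sites[[nm]], reference$ref_mean[match(nm, reference$name)])
  })
  bc <- matrix(bc, nrow = nrow(sites))
  idx <- as.vector(bc %*% (w / sum(w)))
  100 * idx * (1 - 0.2 * sites$invasive_alien_cover / 100)
}

#' Simulate the point-score elicitation
#'
#' Each expert scores `n_common` sites common to the whole panel (chosen a
#' priori to span the condition range) plus a random draw of further sites.
#' Scores are the true score plus an expert intercept plus noise, clipped to
#' \[0, 100\]; offset and BAU futures apply the true MG* and AL* functions
#' of the site's starting condition. Only the first `n_experts_bau` experts
#' score a BAU future.
#'
#' @param sites Output of [simulate_site_pool()].
#' @param config A [generator_config()].
#' @param seed Seed.
#' @return list: `scores` (point-score schema), `truth` (per site true
#'   score, MG*, AL* on 0-100), `experts` (per expert intercept).
#' @export
simulate_point_scores <- function(sites, config = generator_config(), seed = 1) {
  set.seed(seed)
  n_e <- config$n_experts_points
  experts <- sprintf("P%02d", seq_len(n_e))
  intercept <- if (config$expert_intercept_sd > 0)
    stats::rnorm(n_e, 0, config$expert_intercept_sd) else rep(0, n_e)
  # common sites chosen a priori to span expected low through high quality
  ord <- order(sites$true_score)
  qpos <- round(stats::quantile(seq_len(nrow(sites)),
                                probs = seq(0.05, 0.95, length.out = config$n_common)))
  common <- sites$site_id[ord[qpos]]
  bc <- sites$true_score / 100
  mg_true <- 100 * (config$true_mg[["a"]] * (1 - bc) + config$true_mg[["b"]])
  al_true <- 100 * (config$true_al[["a"]] * bc + config$true_al[["b"]])
  truth <- data.frame(site_id = sites$site_id, true_score = sites$true_score,
                      mg_true = mg_true, al_true = al_true,
                      stringsAsFactors = FALSE)
  nz <- function(k) if (config$expert_score_noise_sd > 0)
    stats::rnorm(k, 0, config$expert_score_noise_sd) else 0
  rows <- lapply(seq_len(n_e), function(i) {
    pick <- c(common, sample(setdiff(sites$site_id, common),
                             config$sites_per_expert - config$n_common))
    j <- match(pick, sites$site_id)
    k <- length(j)
    current <- pmin(pmax(sites$true_score[j] + intercept[i] + nz(k), 0), 100)
    fut_off <- pmin(pmax(current + mg_true[j] + nz(k), 0), 100)
    fut_bau <- if (i <= config$n_experts_bau) {
      pmin(pmax(current - al_true[j] + nz(k), 0), 100)
    } else rep(NA_real_, k)
    data.frame(expert_id = experts[i], site_id = pick, current = current,
               future_offset = fut_off, future_bau = fut_bau,
               stringsAsFactors = FALSE)
  })
  list(scores = do.call(rbind, rows), truth = truth,
       experts = data.frame(expert_id = experts, intercept = intercept,
                            stringsAsFactors = FALSE))
}

# subjective distribution for one expert/attribute/state: family + params +
# elicitation interval, from a target mean and sd
.subjective_params <- function(mean_, sd_, family, support_min, support_max) {
  mean_ <- min(max(mean_, support_min + 1e-6), min(support_max, 1e6))
  if (family == "beta_rescaled") {
    m <- min(max(mean_ / 100, 5e-4), 1 - 5e-4)
    s <- min(sd_ / 100, 0.9 * sqrt(m * (1 - m)))
    s <- max(s, 1e-12)
    nu <- m * (1 - m) / s^2 - 1
    nu <- max(nu, 1e-2)
    list(family = family, params = c(m * nu, (1 - m) * nu),
         mean = 100 * m, sd = 100 * s)
  } else {
    list(family = family, params = c(mean_, max(sd_, 1e-12)),
         mean = mean_, sd = max(sd_, 1e-12))
  }
}

.subjective_bin_mass <- function(sub, lower, upper) {
  if (sub$family == "beta_rescaled") {
    stats::pbeta(pmin(pmax(upper / 100, 0), 1), sub$params[1], sub$params[2]) -
      stats::pbeta(pmin(pmax(lower / 100, 0), 1), sub$params[1], sub$params[2])
  } else {
    stats::pnorm(upper, sub$params[1], sub$params[2]) -
      stats::pnorm(lower, sub$params[1], sub$params[2])
  }
}

#' Simulate the roulette elicitation for one scenario
#'
#' For each expert, attribute and elicited state, the expert's subjective
#' distribution is centred on the true state mean shifted by the expert's
#' temporal-optimism term (futures only; the same term moves BAU and offset
#' futures together), with spread equal to the benchmark sd times the
#' overconfidence factor. The elicitation interval is the subjective mean
#' +/- 3 subjective sd clipped to the support; bin masses are discretised to
#' 100 chips by largest-remainder rounding, so every generated record passes
#' validation exactly.
#'
#' @param scenario A scenario from [wsgw_scenarios()].
#' @param config A [generator_config()].
#' @param seed Seed.
#' @param attributes,reference Attribute and benchmark tables.
#' @return list: `elicitations` (schema of [write_elicitations()]), `truth`
#'   (per record: subjective family, mean, sd, expert bias).
#' @export
simulate_roulette_elicitations <- function(scenario,
                                           config = generator_config(),
                                           seed = 1,
                                           attributes = wsgw_attributes(),
                                           reference = wsgw_reference_distributions()) {
  set.seed(seed)
  n_e <- config$n_experts_roulette
  experts <- sprintf("R%02d", seq_len(n_e))
  bias <- if (config$bias_sd > 0) stats::rnorm(n_e, 0, config$bias_sd)
          else rep(0, n_e)
  rows <- list(); truths <- list()
  for (i in seq_len(n_e)) {
    for (a in seq_len(nrow(attributes))) {
      nm <- attributes$name[a]
      family <- choose_family(nm, attributes)
      rmean <- reference$ref_mean[match(nm, reference$name)]
      rsd <- reference$ref_sd[match(nm, reference$name)]
      start <- scenario$start_values[[nm]]
      bc0 <- min(start / rmean, 1)
      mg_star <- config$true_mg[["a"]] * (1 - bc0) + config$true_mg[["b"]]
      al_star <- config$true_al[["a"]] * bc0 + config$true_al[["b"]]
      sub_sd <- rsd * config$overconfidence_factor * config$sd_scale
      state_means <- c(
        reference = rmean,
        future_offset = start + (mg_star + bias[i]) * rmean,
        future_bau = start - (al_star - bias[i]) * rmean
      )
      for (st in scenario$states_elicited) {
        target <- if (st == "reference") state_means[["reference"]] else state_means[[st]]
        sub <- .subjective_params(target, sub_sd, family,
                                  attributes$support_min[a],
                                  attributes$support_max[a])
        tmin <- max(sub$mean - 3 * sub$sd, attributes$support_min[a])
        tmax <- min(sub$mean + 3 * sub$sd, attributes$support_max[a])
        bins <- make_bins(tmin, tmax)
        mass <- .subjective_bin_mass(sub, bins$lower, bins$upper)
        if (sum(mass) <= 0) mass <- rep(1, 10) # fully degenerate: flat
        chips <- largest_remainder(mass, 100L)
        row <- data.frame(expert_id = experts[i], scenario_id = scenario$id,
                          attribute = nm, state = st,
                          theta_min = tmin, theta_max = tmax,
                          stringsAsFactors = FALSE)
        row[.chip_cols] <- as.list(chips)
        rows[[length(rows) + 1L]] <- row
        truths[[length(truths) + 1L]] <- data.frame(
          expert_id = experts[i], scenario_id = scenario$id, attribute = nm,
          state = st, family = sub$family, true_mean = sub$mean,
          true_sd = sub$sd, bias = bias[i], stringsAsFactors = FALSE)
      }
    }
  }
  list(elicitations = do.call(rbind, rows), truth = do.call(rbind, truths))
}
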