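test_that("percentage attributes get rescaled-beta fits, all others normal", {
  expect_equal(choose_family("grass_cover"), "beta_rescaled")
  expect_equal(choose_family("litter_cover"), "beta_rescaled")
  expect_equal(choose_family("forb_richness"), "normal")
  expect_equal(choose_family("log_length"), "normal")
  expect_equal(choose_family("large_trees"), "normal")
  expect_error(choose_family("moss_cover"),
               class = "offsetElicit_validation_error")
})

test_that("a symmetric histogram forces a central normal mean", {
  rec <- roulette_elicitation("e", "sc", "forb_richness", "reference",
                              0, 100, rep(10L, 10))
  f <- fit_distribution(rec)
  expect_equal(f$family, "normal")
  expect_equal(unname(f$params["mu"]), 50, tolerance = 1e-6)
})

test_that("fitting recovers a discretised normal within tolerance and matches the grid oracle", {
  chips <- chips_from_cdf(function(x) pnorm(x, 20, 4), 8, 32)
  rec <- roulette_elicitation("e", "sc", "forb_richness", "reference",
                              8, 32, chips)
  f <- fit_distribution(rec)
  expect_equal(unname(f$params["mu"]), 20, tolerance = 0.5)
  expect_equal(unname(f$params["sigma"]), 4, tolerance = 0.5)

  # independent exhaustive grid search on the same objective agrees
  edges <- seq(8, 32, length.out = 11)[2:10]
  cp <- cumsum(chips / 100)[1:9]
  g <- oracle_grid_normal(edges, cp, seq(15, 25, by = 0.05), seq(2, 7, by = 0.05))
  expect_equal(unname(f$params["mu"]), unname(g["mu"]), tolerance = 0.1)
  expect_equal(unname(f$params["sigma"]), unname(g["sd"]), tolerance = 0.1)
  expect_lte(f$fit_sse, g[["sse"]] + 1e-8)  # at least as good as the grid
})

test_that("a symmetric cover histogram yields a symmetric beta fit", {
  chips <- chips_from_cdf(function(x) pbeta(x / 100, 3, 3), 0, 100)
  rec <- roulette_elicitation("e", "sc", "grass_cover", "reference",
                              0, 100, chips)
  f <- fit_distribution(rec)
  expect_equal(f$family, "beta_rescaled")
  expect_equal(unname(f$params["alpha"]), unname(f$params["beta"]),
               tolerance = 1e-3)
  edges01 <- seq(0.1, 0.9, by = 0.1)
  cp <- cumsum(chips / 100)[1:9]
  g <- oracle_grid_beta(edges01, cp, seq(2, 4.5, by = 0.02), seq(2, 4.5, by = 0.02))
  expect_lte(f$fit_sse, g[["sse"]] + 1e-8)
  expect_equal(unname(f$params["alpha"]), unname(g["alpha"]), tolerance = 0.1)
})

test_that("fitted parameters beat perturbed parameters on the fit objective", {
  # local optimality: perturbing the fitted pair never lowers the SSE
  chips <- chips_from_cdf(function(x) pnorm(x, 55, 9), 30, 85)
  rec <- roulette_elicitation("e", "sc", "log_length", "reference",
                              30, 85, chips)
  f <- fit_distribution(rec)
  edges <- seq(30, 85, length.out = 11)[2:10]
  cp <- cumsum(chips / 100)[1:9]
  for (d in list(c(.5, 0), c(-.5, 0), c(0, .5), c(0, -.5), c(.3, .3), c(-.3, -.3))) {
    expect_lte(f$fit_sse,
               oracle_sse_normal(f$params["mu"] + d[1], f$params["sigma"] + d[2],
                                 edges, cp) + 1e-10)
  }
})

test_that("single-bin histograms get midpoint location and a minimum spread", {
  chips <- integer(10); chips[4] <- 100L
  rec <- roulette_elicitation("e", "sc", "forb_richness", "reference",
                              0, 100, chips)
  f <- fit_distribution(rec)
  expect_true(f$single_bin)
  expect_equal(unname(f$params["mu"]), 35)       # midpoint of bin 4
  expect_equal(unname(f$params["sigma"]), 2.5)   # (bin width)/4

  # beta analogue keeps its mean at the bin midpoint
  recb <- roulette_elicitation("e", "sc", "grass_cover", "reference",
                               0, 100, chips)
  fb <- fit_distribution(recb)
  expect_equal(100 * fb$params[["alpha"]] / sum(fb$params), 35, tolerance = 1e-6)
})

test_that("sampling respects supports, seeds and degenerate limits", {
  # degenerate-limit normal: all draws at the location
  f <- list(family = "normal", params = c(10, 1e-12))
  x <- sample_fitted(f, 100, "forb_richness")
  expect_true(all(abs(x - 10) < 1e-9))

  # clipping floors count draws at zero
  f2 <- list(family = "normal", params = c(1, 2))
  set.seed(1)
  x2 <- sample_fitted(f2, 1e4, "forb_richness")
  expect_gte(min(x2), 0)
  expect_gt(attr(x2, "clipped_fraction"), 0)

  # symmetric rescaled beta has mean 50 (analytic alpha/(alpha+beta))
  f3 <- list(family = "beta_rescaled", params = c(2, 2))
  set.seed(2)
  x3 <- sample_fitted(f3, 1e5, "grass_cover")
  expect_equal(mean(x3), 50, tolerance = 0.5)

  # identical seed, identical draws; interior distributions are unclipped
  f4 <- list(family = "normal", params = c(50, 3))
  set.seed(7); a <- sample_fitted(f4, 1000, "forb_richness")
  set.seed(7); b <- sample_fitted(f4, 1000, "forb_richness")
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(attr(a, "clipped_fraction"), 0)
})

test_that("multimodality flags separated strict peaks but not plateaus", {
  two_peaks <- roulette_elicitation("e", "sc", "grass_cover", "reference",
    0, 100, c(0, 30, 0, 0, 0, 0, 0, 30, 0, 40))
  mm <- detect_multimodality(two_peaks)
  expect_true(mm$multimodal)
  expect_true(all(c(2, 8) %in% mm$modes))

  unimodal <- roulette_elicitation("e", "sc", "grass_cover", "reference",
    0, 100, c(5, 10, 20, 30, 20, 10, 5, 0, 0, 0))
  expect_false(detect_multimodality(unimodal)$multimodal)

  plateau <- roulette_elicitation("e", "sc", "grass_cover", "reference",
    0, 100, rep(10L, 10))
  mm <- detect_multimodality(plateau)
  expect_false(mm$multimodal)
  expect_length(mm$modes, 0)
})

test_that("fit_elicitations is deterministic and carries flags through", {
  panel <- small_panel(seed = 5, n_experts = 3)
  f1 <- fit_elicitations(panel$elicitations, panel$attributes)
  f2 <- fit_elicitations(panel$elicitations, panel$attributes)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), nrow(panel$elicitations))
  expect_true(all(f1$fit_sse >= 0))
  expect_true(all(f1$param2 > 0))
  # families follow the attribute category for every record
  expect_equal(f1$family,
               ifelse(f1$attribute %in% c("grass_cover"), "beta_rescaled", "normal"))
})
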