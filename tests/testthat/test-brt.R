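make_score_panel <- function(seed = 1, config = generator_config()) {
  sites <- simulate_site_pool(config, seed = seed)
  ps <- simulate_point_scores(sites, config, seed = seed + 1)
  list(sites = sites, scores = ps$scores, truth = ps$truth)
}

test_that("the model table has one row per expert-site and the stated covariates", {
  p <- make_score_panel(seed = 2)
  d <- build_design(p$scores, p$sites, response = "current")
  expect_equal(length(d$y), 29 * 15)            # 435 rows
  expect_equal(length(d$covariates), 17)        # 13 attributes + 3 covers + expert
  expect_true("expert_id" %in% d$covariates)
  expect_s3_class(d$x$expert_id, "factor")

  dmg <- build_design(p$scores, p$sites, response = "MG")
  expect_equal(length(dmg$covariates), 18)      # adds the expert's current score
  expect_true("current_score" %in% dmg$covariates)

  dal <- build_design(p$scores, p$sites, response = "AL")
  expect_equal(length(dal$y), 16 * 15)          # only the 16 BAU experts remain
  expect_false(anyNA(dal$y))
})

test_that("a score for an undescribed site is an error", {
  p <- make_score_panel(seed = 3)
  rogue <- p$scores[1, ]; rogue$site_id <- "S99"
  expect_error(build_design(rbind(p$scores, rogue), p$sites, "current"), "S99")
})

test_that("designs and fits are invariant to input row order", {
  p <- make_score_panel(seed = 4)
  d1 <- build_design(p$scores, p$sites, "current")
  set.seed(99)
  d2 <- build_design(p$scores[sample(nrow(p$scores)), ], p$sites, "current")
  expect_equal(d1$x, d2$x, ignore_attr = TRUE)
  expect_equal(d1$y, d2$y)

  # the small tree budget may cap the ensemble; capping equally is fine here
  f1 <- suppressWarnings(fit_brt(d1, fast_brt(seed = 11)))
  f2 <- suppressWarnings(fit_brt(d2, fast_brt(seed = 11)))
  expect_equal(relative_influence(f1)$NRI, relative_influence(f2)$NRI)
})

test_that("a constant response yields a constant ensemble with no splits", {
  p <- make_score_panel(seed = 5)
  d <- build_design(p$scores, p$sites, "current")
  d$y <- rep(42, length(d$y))
  f <- fit_brt(d, fast_brt())
  expect_equal(f$n_trees, 0L)
  pred <- predict_condition(f, p$sites)
  expect_equal(pred$predicted, rep(42, nrow(p$sites)), tolerance = 1e-6)
  expect_equal(pred$spread, rep(0, nrow(p$sites)))
  expect_error(relative_influence(f), "no splits")
})

test_that("relative influence normalises to 100 and concentrates on the signal", {
  set.seed(21)
  n <- 1000
  x <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n), x4 = runif(n))
  y <- 3 * x$x1 + rnorm(n, 0, 0.1)
  train <- 1:800
  f <- fit_brt(num_design(x[train, ], y[train]), fast_brt(seed = 2))
  ri <- relative_influence(f)
  expect_equal(sum(ri$NRI), 100, tolerance = 1e-6)
  expect_equal(ri$covariate[1], "x1")
  expect_gt(ri$NRI[1], 90)

  # held-out accuracy on the single informative covariate
  Xnew <- as.matrix(x[-train, ])
  pred <- predict(f$booster, xgboost::xgb.DMatrix(Xnew))
  r2 <- 1 - mean((y[-train] - pred)^2) / var(y[-train])
  expect_gt(r2, 0.8)

  # a pure-noise covariate barely moves held-out accuracy
  x5 <- x; x5$x5 <- runif(n)
  f5 <- fit_brt(num_design(x5[train, ], y[train]), fast_brt(seed = 2))
  pred5 <- predict(f5$booster, xgboost::xgb.DMatrix(as.matrix(x5[-train, ])))
  r2_5 <- 1 - mean((y[-train] - pred5)^2) / var(y[-train])
  expect_lt(abs(r2 - r2_5), 0.05)
})

test_that("a shuffled response carries no cross-validated signal", {
  set.seed(31)
  n <- 400
  x <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- sample(3 * x$x1 + rnorm(n, 0, 0.1))  # permutation breaks the link
  f <- fit_brt(num_design(x, y), fast_brt(seed = 3))
  expect_gte(min(f$cv_deviance_profile), 0.9 * sd(y))
})

test_that("exchangeable near-duplicate covariates share the influence", {
  shares <- vapply(1:3, function(seed) {
    set.seed(seed)
    n <- 500
    x1 <- runif(n)
    x <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.01), x3 = runif(n))
    y <- 2 * x1 + rnorm(n, 0, 0.05)
    ri <- relative_influence(fit_brt(num_design(x, y), fast_brt(seed = seed)))
    ri$NRI[ri$covariate == "x1"] /
      sum(ri$NRI[ri$covariate %in% c("x1", "x2")])
  }, numeric(1))
  expect_equal(mean(shares) * 100, 50, tolerance = 15)
})

test_that("partial dependence tracks additive structure", {
  set.seed(41)
  n <- 600
  x <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1),
                  x3 = runif(n, -1, 1))
  f_mono <- fit_brt(num_design(x, x$x1 + 0.05 * rnorm(n)), fast_brt(seed = 4))
  pd <- fitted_function(f_mono, "x1", grid = seq(-0.9, 0.9, length.out = 13))
  expect_gt(cor(pd$value, pd$partial_dependence, method = "spearman"), 0.95)
  expect_gt(pd$partial_dependence[13], pd$partial_dependence[1])

  # a covariate the trees never split on has a flat fitted function
  pd3 <- fitted_function(f_mono, "x3", grid = seq(-0.9, 0.9, length.out = 9))
  expect_lt(diff(range(pd3$partial_dependence)),
            0.05 * diff(range(pd$partial_dependence)))

  # symmetric V-shaped response gives a symmetric fitted function
  f_v <- fit_brt(num_design(x, abs(x$x1) + 0.05 * rnorm(n)), fast_brt(seed = 5))
  g <- seq(-0.8, 0.8, length.out = 9)
  pdv <- fitted_function(f_v, "x1", grid = g)$partial_dependence
  expect_equal(pdv, rev(pdv), tolerance = 0.15)

  expect_error(fitted_function(f_mono, "nope"), "unknown covariate")
})

test_that("ensemble condition predictions average members and clip to the scale", {
  p <- make_score_panel(seed = 6)
  d <- build_design(p$scores, p$sites, "current")
  f1 <- fit_brt(d, fast_brt(seed = 7))
  one <- predict_condition(f1, p$sites[1:5, ])
  expect_equal(one$spread, rep(0, 5))
  expect_true(all(one$predicted >= 0 & one$predicted <= 100))

  f2 <- fit_brt(d, fast_brt(seed = 8))
  two <- predict_condition(list(f1, f2), p$sites[1:5, ])
  m1 <- predict_condition(f1, p$sites[1:5, ])$predicted
  m2 <- predict_condition(f2, p$sites[1:5, ])$predicted
  expect_equal(two$predicted, (m1 + m2) / 2, tolerance = 1e-9)
  expect_true(all(two$spread >= 0))

  # predictions track the generator's truth within its noise envelope
  all_pred <- predict_condition(f1, p$sites)
  expect_gt(cor(all_pred$predicted, p$truth$true_score), 0.8)

  expect_error(predict_condition(f1, p$sites[, 1:4]), "missing covariate")
})
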