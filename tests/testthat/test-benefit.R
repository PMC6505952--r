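test_that("condition scores are capped ratios on [0, 1]", {
  expect_equal(condition_score(60, 60), 1)
  expect_equal(condition_score(0, 60), 0)
  expect_equal(condition_score(30, 60), 0.5)
  expect_equal(condition_score(120, 60), 1)  # cap when V >= R
  expect_error(condition_score(-1, 60))
  expect_error(condition_score(10, 0))

  # vectorised, bounded, and monotone in the value for fixed reference
  set.seed(3)
  v <- sort(runif(100, 0, 200)); r <- 75
  bc <- condition_score(v, r)
  expect_true(all(bc >= 0 & bc <= 1))
  expect_true(all(diff(bc) >= 0))
})

test_that("point-score benefit arithmetic follows the benefit model", {
  b <- aggregate_point_benefit(point_score_record("e", "s", 60, 70, 50))
  expect_equal(b, list(MG = 10, AL = 10, TB = 20))

  b2 <- aggregate_point_benefit(point_score_record("e", "s", 84, 84))
  expect_equal(b2$MG, 0)
  expect_true(is.na(b2$AL) && is.na(b2$TB))

  # negative benefits are permitted and preserved
  b3 <- aggregate_point_benefit(point_score_record("e", "s", 39, 30, 45))
  expect_equal(b3, list(MG = -9, AL = -6, TB = -15))
})

test_that("pooled sample count is exactly experts times draws", {
  fits <- rbind(
    do.call(rbind, lapply(sprintf("e%d", 1:4), function(e) rbind(
      fit_row(e, "forb_richness", "reference", "normal", 25, 5),
      fit_row(e, "forb_richness", "future_offset", "normal", 22, 5),
      fit_row(e, "forb_richness", "future_bau", "normal", 18, 5)))))
  s <- pooled_benefit(fits, c(forb_richness = 20), draws_per_expert = 10, seed = 1)
  expect_equal(nrow(s), 4 * 10)
  expect_equal(as.integer(table(s$expert_id)), rep(10L, 4))
})

test_that("total benefit is exactly averted loss plus management gain", {
  panel <- small_panel(seed = 21, n_experts = 5)
  fits <- fit_elicitations(panel$elicitations, panel$attributes)
  s <- pooled_benefit(fits, panel$scenario$start_values, draws_per_expert = 30,
                      seed = 2, attributes = panel$attributes)
  expect_identical(s$TB, s$AL + s$MG)      # exact identity, not approximate
  expect_true(all(s$BC_start >= 0 & s$BC_start <= 1))
  expect_true(all(s$BC_offset >= 0 & s$BC_offset <= 1))
  expect_true(all(s$BC_bau >= 0 & s$BC_bau <= 1, na.rm = TRUE))
  expect_true(all(abs(s$MG) <= 1 & abs(s$TB[!is.na(s$TB)]) <= 2))
})

test_that("degenerate no-change distributions give zero benefit", {
  eps <- 1e-9
  fits <- do.call(rbind, lapply(c("e1", "e2"), function(e) rbind(
    fit_row(e, "forb_richness", "reference", "normal", 20, eps),
    fit_row(e, "forb_richness", "future_offset", "normal", 20, eps),
    fit_row(e, "forb_richness", "future_bau", "normal", 20, eps))))
  s <- pooled_benefit(fits, c(forb_richness = 20), draws_per_expert = 50, seed = 3)
  expect_true(all(abs(s$AL) < 1e-6))
  expect_true(all(abs(s$MG) < 1e-6))
  expect_true(all(abs(s$TB) < 1e-6))
})

test_that("an offset future dominated by the reference yields negative expected gain", {
  # offset distribution sits below the reference; start at the reference mean,
  # so BC_start is capped near 1 and management gain must be negative on average
  fits <- rbind(
    fit_row("e1", "forb_richness", "reference", "normal", 50, 5),
    fit_row("e1", "forb_richness", "future_offset", "normal", 40, 5))
  s <- pooled_benefit(fits, c(forb_richness = 50), draws_per_expert = 1e4, seed = 4)
  expect_lt(mean(s$MG), 0)
})

test_that("a missing reference fit for a contributing expert is an error", {
  fits <- rbind(
    fit_row("e1", "forb_richness", "reference", "normal", 25, 5),
    fit_row("e1", "forb_richness", "future_offset", "normal", 22, 5),
    fit_row("e2", "forb_richness", "future_offset", "normal", 22, 5))
  expect_error(pooled_benefit(fits, c(forb_richness = 20), 10, seed = 1), "e2")
})

test_that("raising every offset future never lowers the pooled median gain", {
  base <- small_panel(seed = 31, n_experts = 4,
                      states = c("reference", "future_offset"))
  fits <- fit_elicitations(base$elicitations, base$attributes)
  shifted <- fits
  up <- shifted$state == "future_offset" & shifted$family == "normal"
  shifted$param1[up] <- shifted$param1[up] + 3
  # same seed, so draws are coupled; the shift acts stochastically upward
  for (a in unique(fits$attribute)) {
    if (choose_family(a) != "normal") next
    m0 <- median(pooled_benefit(fits[fits$attribute == a, ],
                                base$scenario$start_values[a],
                                100, seed = 5)$MG)
    m1 <- median(pooled_benefit(shifted[shifted$attribute == a, ],
                                base$scenario$start_values[a],
                                100, seed = 5)$MG)
    expect_gte(m1, m0)
  }
})

test_that("benefit summaries report quartiles and signed fractions", {
  s <- sample_rows("e1", "a", AL = c(-1, 0, 1), MG = 0)
  out <- summarize_benefit(s)
  expect_equal(out$fraction_negative_TB, 1 / 3)
  expect_equal(out$fraction_zero_TB, 1 / 3)

  sc <- sample_rows("e1", "a", AL = rep(0.2, 5), MG = rep(0.1, 5))
  outc <- summarize_benefit(sc)
  expect_equal(outc$TB_q25, outc$TB_median)
  expect_equal(outc$TB_median, outc$TB_q75)

  set.seed(9)
  sn <- sample_rows("e1", "a", AL = 0, MG = rnorm(2100, 0.05, 0.1))
  sn$TB <- sn$MG  # TB draws from a known normal
  outn <- summarize_benefit(sn)
  expect_equal(outn$TB_median, 0.05, tolerance = 0.01)
  expect_error(summarize_benefit(sn[0, ]))
})

test_that("mg_vs_start reproduces point arithmetic for degenerate panels", {
  eps <- 1e-9
  R <- 80; start <- 40; v_off <- 52; v_bau <- 33
  fits <- rbind(
    fit_row("e1", "forb_richness", "reference", "normal", R, eps),
    fit_row("e1", "forb_richness", "future_offset", "normal", v_off, eps),
    fit_row("e1", "forb_richness", "future_bau", "normal", v_bau, eps))
  s <- pooled_benefit(fits, c(forb_richness = start), draws_per_expert = 20,
                      seed = 6)
  pt <- aggregate_point_benefit(point_score_record("e1", "s", start, v_off, v_bau))
  expect_equal(median(s$MG), pt$MG / R, tolerance = 1e-6)
  expect_equal(median(s$AL), pt$AL / R, tolerance = 1e-6)
  tab <- mg_vs_start(s)
  expect_equal(tab$BC_start_median, start / R, tolerance = 1e-6)
  expect_equal(tab$MG_median, (v_off - start) / R, tolerance = 1e-6)
})
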