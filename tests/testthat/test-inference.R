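# stack per-pillar score vectors into one long frame
stack_scores <- function(...) {
  parts <- list(...)
  do.call(rbind, lapply(names(parts), function(p) toy_scores(parts[[p]], p)))
}

test_that("one-way F matches the hand sums-of-squares oracle", {
  reg <- toy_registry(c(C = 3, E = 3))
  x <- stats::setNames(c(1, 2, 3, 4, 5, 6), reg$region_id)
  mv <- zonal_manova(toy_scores(x), reg)
  oracle <- oracle_oneway_F(unname(x), rep(c("C", "E"), each = 3))
  expect_equal(mv$univariate$F, 13.5)
  expect_equal(mv$univariate$F, oracle$F)
  expect_equal(mv$univariate$df_between, oracle$df1)  # 1
  expect_equal(mv$univariate$df_within, oracle$df2)   # 4

  # and on random multi-zone data
  set.seed(808)
  reg2 <- toy_registry(c(C = 4, E = 5, N = 6))
  y <- stats::setNames(runif(15, 0, 100), reg2$region_id)
  mv2 <- zonal_manova(toy_scores(y), reg2)
  o2 <- oracle_oneway_F(unname(y), as.character(reg2$zone))
  expect_equal(mv2$univariate$F, o2$F)
  expect_equal(mv2$univariate$p,
               stats::pf(o2$F, o2$df1, o2$df2, lower.tail = FALSE))
})

test_that("with two zones the univariate F equals the squared t statistic", {
  set.seed(909)
  for (rep in 1:5) {
    reg <- toy_registry(c(C = 5, S = 7))
    x <- stats::setNames(runif(12, 0, 100), reg$region_id)
    mv <- zonal_manova(toy_scores(x), reg)
    tt <- stats::t.test(x[1:5], x[6:12], var.equal = TRUE)
    expect_equal(mv$univariate$F, unname(tt$statistic)^2)
    expect_equal(mv$univariate$p, tt$p.value)
  }
})

test_that("MANOVA reports Pillai's trace and per-pillar tests with shared dfs", {
  sim <- generate_survey(synthetic_config(seed = 21))
  cfg <- synthetic_pillar_config(synthetic_config())
  scores <- score_all(sim$table, cfg, sim$registry)
  mv <- zonal_manova(scores, sim$registry)
  expect_equal(mv$pillai$name, "Pillai")
  expect_gte(mv$pillai$statistic, 0)
  expect_lte(mv$pillai$p, 1)
  expect_equal(mv$univariate$df_between, rep(5L, 3))
  expect_equal(mv$univariate$df_within, rep(65L, 3))
  expect_true(all(mv$univariate$F >= 0))

  # cross-check each univariate F against independent per-pillar aov fits
  d <- data.frame(zone = sim$registry$zone)
  for (p in c("MHU", "WE", "DC")) {
    d$y <- scores$score[scores$pillar_id == p][
      match(sim$registry$region_id,
            scores$region_id[scores$pillar_id == p])]
    ref <- stats::anova(stats::lm(y ~ zone, data = d))
    expect_equal(mv$univariate$F[mv$univariate$pillar_id == p], ref$`F value`[1])
  }
})

test_that("MANOVA validates its preconditions", {
  reg <- toy_registry(c(C = 1, E = 3))
  x <- stats::setNames(c(1, 4, 5, 6), reg$region_id)
  expect_error(zonal_manova(toy_scores(x), reg), "C")
  # zero within-zone variance everywhere leaves F undefined
  reg2 <- toy_registry(c(C = 2, E = 2))
  flat <- stats::setNames(c(3, 3, 8, 8), reg2$region_id)
  expect_error(zonal_manova(toy_scores(flat), reg2), "variance")
  # regions with any undefined pillar score are excluded listwise
  reg3 <- toy_registry(c(C = 3, E = 3))
  sc <- stack_scores(
    MHU = stats::setNames(c(1, 2, 3, 6, 5, 4), reg3$region_id),
    WE = stats::setNames(c(9, 7, NA, 5, 6, 8), reg3$region_id))
  mv <- zonal_manova(sc, reg3)
  expect_equal(mv$n, 5L)
  expect_equal(mv$univariate$df_within, rep(3L, 2))
})

test_that("bonferroni post-hoc compares all pairs with the pooled error term", {
  sim <- generate_survey(synthetic_config(seed = 22))
  cfg <- synthetic_pillar_config(synthetic_config())
  scores <- score_all(sim$table, cfg, sim$registry)
  ph <- bonferroni_posthoc(scores, sim$registry, "MHU")
  expect_equal(nrow(ph), choose(6, 2))  # 15 unordered zone pairs
  expect_true(all(ph$p_adj >= ph$p))
  expect_true(all(ph$p_adj <= 1))

  # independent oracle: pairwise t tests on the pooled sd with Bonferroni
  x <- scores$score[scores$pillar_id == "MHU"]
  z <- sim$registry$zone[match(scores$region_id[scores$pillar_id == "MHU"],
                               sim$registry$region_id)]
  ref <- stats::pairwise.t.test(x, z, p.adjust.method = "bonferroni",
                                pool.sd = TRUE)$p.value
  for (i in seq_len(nrow(ph))) {
    a <- ph$zone_a[i]; b <- ph$zone_b[i]
    ref_p <- if (!is.na(ref[b, a])) ref[b, a] else ref[a, b]
    expect_equal(ph$p_adj[i], unname(ref_p), tolerance = 1e-12)
  }
})

test_that("post-hoc direction convention and antisymmetry hold", {
  reg <- toy_registry(c(C = 3, E = 3))
  x <- stats::setNames(c(1, 2, 3, 4, 5, 6), reg$region_id)  # means 2 and 5
  ph <- bonferroni_posthoc(toy_scores(x), reg, "MHU")
  expect_equal(ph$mean_diff, -3)  # first-listed zone minus second

  # swapping the registry's zone labels flips the sign, not the p-value
  reg_sw <- reg; reg_sw$zone <- factor(rev(as.character(reg$zone)), levels = levels(reg$zone))
  ph_sw <- bonferroni_posthoc(toy_scores(x), reg_sw, "MHU")
  expect_equal(ph_sw$mean_diff, 3)
  expect_equal(ph_sw$p_adj, ph$p_adj)
})

test_that("identical zone means give p_adj 1 and no significant pairs", {
  reg <- toy_registry(c(C = 3, E = 3, N = 3))
  x <- stats::setNames(c(1, 2, 3, 1, 2, 3, 1, 2, 3), reg$region_id)
  ph <- bonferroni_posthoc(toy_scores(x), reg, "MHU")
  expect_true(all(ph$p_adj == 1))
  expect_false(any(ph$significant))
})

test_that("post-hoc recovers injected pairwise shifts on strong signal", {
  zm <- default_zone_means()
  zm[] <- 50; zm["S", ] <- 90   # only pairs involving S truly differ
  cfg <- synthetic_config(zone_means = zm, indicator_sd = 1, region_sd = 3,
                          seed = 23)
  sim <- generate_survey(cfg)
  scores <- score_all(sim$table, synthetic_pillar_config(cfg), sim$registry)
  ph <- bonferroni_posthoc(scores, sim$registry, "MHU")
  involves_S <- ph$zone_a == "S" | ph$zone_b == "S"
  expect_true(all(ph$significant[involves_S]))
  expect_false(any(ph$significant[!involves_S]))
})

test_that("regression reproduces closed-form OLS cases", {
  reg <- toy_registry(c(C = 3))
  sc <- stack_scores(WE = stats::setNames(c(0, 1, 2) * 10, reg$region_id),
                     MHU = stats::setNames(c(1, 3, 5) * 10, reg$region_id))
  r <- fit_we_mhu_regression(sc, reg)
  expect_equal(r$intercept, 10)
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  expect_equal(r$n, 3L)

  # symmetric vee: slope 0, nothing explained
  sc2 <- stack_scores(WE = stats::setNames(c(0, 10, 20), reg$region_id),
                      MHU = stats::setNames(c(0, 10, 0), reg$region_id))
  r2 <- fit_we_mhu_regression(sc2, reg)
  expect_equal(r2$slope, 0)
  expect_equal(r2$r_squared, 0)

  # constant response: flat line, zero R^2
  sc3 <- stack_scores(WE = stats::setNames(c(0, 10, 20), reg$region_id),
                      MHU = stats::setNames(c(5, 5, 5), reg$region_id))
  r3 <- fit_we_mhu_regression(sc3, reg)
  expect_equal(r3$slope, 0)
  expect_equal(r3$r_squared, 0)

  # zero predictor variance is an error
  sc4 <- stack_scores(WE = stats::setNames(c(7, 7, 7), reg$region_id),
                      MHU = stats::setNames(c(1, 2, 3), reg$region_id))
  expect_error(fit_we_mhu_regression(sc4, reg), "variance")
})

test_that("R squared is invariant under affine rescaling of the predictor", {
  set.seed(111)
  reg <- toy_registry(c(C = 10))
  we <- runif(10, 20, 80)
  mhu <- 0.5 * we + rnorm(10, 0, 5)
  sc <- stack_scores(WE = stats::setNames(we, reg$region_id),
                     MHU = stats::setNames(mhu, reg$region_id))
  r <- fit_we_mhu_regression(sc, reg)
  sc2 <- stack_scores(WE = stats::setNames(0.3 * we + 11, reg$region_id),
                      MHU = stats::setNames(mhu, reg$region_id))
  r2 <- fit_we_mhu_regression(sc2, reg)
  expect_equal(r$r_squared, r2$r_squared)
  expect_equal(r$r_squared, stats::cor(we, mhu)^2)
})
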