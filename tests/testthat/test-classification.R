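test_that("equally spaced distinct scores split two per quantile, any order", {
  base <- 1:8
  for (rep in 1:10) {
    perm <- sample(base)
    sc <- toy_scores(stats::setNames(perm, paste0("u_C", seq_along(perm))))
    asn <- assign_quantiles(sc)
    counts <- table(asn$quantile)
    expect_equal(as.integer(counts), rep(2L, 4))
    # each region lands where the sort-and-split oracle puts it
    expect_equal(as.integer(sub("Q", "", asn$quantile)),
                 oracle_quantile_bins(perm))
  }
})

test_that("quantile assignment matches the sort-and-split oracle exhaustively", {
  # all permutations at n = 5 (120), random draws up to n = 10
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  vals <- c(12, 40, 40, 77, 95)   # includes a tie
  for (p in perms(vals)) {
    sc <- toy_scores(stats::setNames(p, paste0("u_C", 1:5)))
    asn <- assign_quantiles(sc)
    expect_equal(as.integer(sub("Q", "", asn$quantile)), oracle_quantile_bins(p))
  }
  set.seed(505)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- round(runif(n, 0, 100), 1)
    sc <- toy_scores(stats::setNames(x, paste0("u_C", 1:n)))
    asn <- assign_quantiles(sc)
    expect_equal(as.integer(sub("Q", "", asn$quantile)), oracle_quantile_bins(x))
  }
})

test_that("boundary and degenerate cases follow the documented conventions", {
  # all identical scores: every region is Q1 (ties go to the lower bin)
  sc <- toy_scores(stats::setNames(rep(50, 6), paste0("u_C", 1:6)))
  expect_true(all(assign_quantiles(sc)$quantile == "Q1"))

  # supplied cutpoints are half-open on the left: score == cutpoint stays low
  sc2 <- toy_scores(c(u_C1 = 70, u_C2 = 70.01, u_C3 = 30, u_C4 = 50))
  asn <- assign_quantiles(sc2, cutpoints = c(30, 50, 70))
  got <- stats::setNames(asn$quantile, asn$region_id)
  expect_equal(unname(got[c("u_C1", "u_C2", "u_C3", "u_C4")]),
               c("Q3", "Q4", "Q1", "Q2"))

  # labels follow the fixed quantile -> label mapping
  expect_equal(unique(asn$label[asn$quantile == "Q4"]), "excellent")
  expect_equal(unique(asn$label[asn$quantile == "Q1"]), "poor")

  # undefined scores receive no assignment
  sc3 <- toy_scores(c(u_C1 = 10, u_C2 = 20, u_C3 = 30, u_C4 = 40, u_C5 = NA))
  expect_false("u_C5" %in% assign_quantiles(sc3)$region_id)

  expect_error(assign_quantiles(sc2, cutpoints = c(50, 30, 70)), "ascending")
  expect_error(assign_quantiles(toy_scores(c(u_C1 = 1, u_C2 = 2, u_C3 = 3))),
               "at least 4")
})

test_that("per pillar, quantile counts partition the defined scores", {
  set.seed(606)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 100)
    x[sample(n, sample(0:2, 1))] <- NA
    sc <- toy_scores(stats::setNames(x, paste0("u_C", 1:n)))
    asn <- assign_quantiles(sc)
    expect_equal(nrow(asn), sum(!is.na(x)))
    expect_equal(length(unique(asn$region_id)), sum(!is.na(x)))
  }
})

test_that("favourability score reproduces the published zone percentages", {
  expect_equal(favourability_score(15, 17), 88.2)
  expect_equal(favourability_score(5, 16), 31.3)   # 31.25 rounds half up
  expect_equal(favourability_score(0, 12), 0)
  expect_equal(favourability_score(16, 16), 100)
  expect_error(favourability_score(1, 0), "zero regions")
  expect_error(favourability_score(5, 4), "n_q34")
})

test_that("rounding matches the decimal-string half-away-from-zero oracle", {
  sweep <- seq(0.05, 99.95, by = 0.1)   # every x.x5 value
  expect_equal(round_half_up(sweep, 1),
               vapply(sweep, oracle_round_string, numeric(1), digits = 1))
  neg <- -c(19.415, 19.414999, 0.05, 2.675)
  expect_equal(round_half_up(neg, 2),
               vapply(neg, oracle_round_string, numeric(1), digits = 2))
})

test_that("favourability table covers zone x pillar and counts correctly", {
  reg <- toy_registry(c(C = 3, S = 2))
  asn <- assign_quantiles(toy_scores(
    c(u_C1 = 10, u_C2 = 55, u_C3 = 80, u_S1 = 90, u_S2 = 99)))
  fav <- favourability(asn, reg)
  expect_equal(nrow(fav), 2L)   # 2 zones x 1 pillar
  expect_equal(fav$n_total, c(3L, 2L))
  # registry regions with no assignment still count in n_total
  reg4 <- toy_registry(c(C = 4, S = 2))
  fav4 <- favourability(asn, reg4)
  expect_equal(fav4$n_total[fav4$zone == "C"], 4L)
  expect_equal(fav4$n_q34[fav4$zone == "C"], fav$n_q34[fav$zone == "C"])
})

test_that("raising a region's score weakly raises quantile and favourability", {
  set.seed(707)
  reg <- toy_registry(c(C = 4, E = 4))
  x <- stats::setNames(runif(8, 0, 100), reg$region_id)
  for (rep in 1:10) {
    target <- sample(names(x), 1)
    x2 <- x
    x2[target] <- min(100, x[target] + runif(1, 0, 40))
    q1 <- assign_quantiles(toy_scores(x))
    q2 <- assign_quantiles(toy_scores(x2))
    bin <- function(asn, id) as.integer(sub("Q", "", asn$quantile[asn$region_id == id]))
    expect_gte(bin(q2, target), bin(q1, target))
    z <- as.character(reg$zone[reg$region_id == target])
    f1 <- favourability(q1, reg); f2 <- favourability(q2, reg)
    expect_gte(f2$score[f2$zone == z], f1$score[f1$zone == z])
  }
})

test_that("quantile occupancy shares sum to 100 per pillar", {
  sim <- generate_survey(synthetic_config(seed = 31))
  cfg <- synthetic_pillar_config(synthetic_config())
  asn <- assign_quantiles(score_all(sim$table, cfg, sim$registry))
  occ <- quantile_occupancy(asn)
  for (p in unique(occ$pillar_id)) {
    expect_equal(sum(occ$n[occ$pillar_id == p]), 71L)
    expect_equal(sum(occ$share[occ$pillar_id == p]), 100, tolerance = 0.02)
  }
})
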