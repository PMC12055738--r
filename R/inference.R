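#' Zonal MANOVA on pillar scores
#'
#' Tests for zonal differences in the pillar score vectors. Regions
#' missing any pillar score are excluded listwise (the multivariate test
#' needs complete response vectors). The omnibus multivariate statistic
#' is Pillai's trace; alongside it, each pillar gets the one-way
#' between-zones F test with `df_between = zones - 1` and
#' `df_within = regions - zones`.
#'
#' @param scores a `pillar_scores` data.frame from [score_all()].
#' @param registry region registry resolving every scored region.
#' @return an object of class `zonal_manova`: list with `pillai`
#'   (name, statistic, df, p), `univariate` (data.frame `pillar_id`, `F`,
#'   `df_between`, `df_within`, `p`), `n`, `zones`, and `fit` (the
#'   underlying [stats::manova()] fit).
#' @export
zonal_manova <- function(scores, registry) {
  d <- manova_frame(scores, registry)
  Y <- as.matrix(d[, setdiff(names(d), c("region_id", "zone")), drop = FALSE])
  if (ncol(Y) > 1L) {
    fit <- stats::manova(Y ~ zone, data = d)
    mv <- summary(fit, test = "Pillai")$stats
    pillai <- list(name = "Pillai", statistic = unname(mv["zone", "Pillai"]),
                   F = unname(mv["zone", "approx F"]),
                   df = unname(c(mv["zone", "num Df"], mv["zone", "den Df"])),
                   p = unname(mv["zone", "Pr(>F)"]))
    uni <- stats::summary.aov(fit)
  } else {
    # single pillar: the multivariate statistic degenerates to the
    # one-way ANOVA, so only the univariate F is reported
    fit <- stats::aov(Y[, 1] ~ zone, data = d)
    pillai <- NULL
    uni <- list(stats::summary.aov(fit)[[1]])
  }
  uni_df <- do.call(rbind, lapply(seq_along(uni), function(i) {
    tab <- uni[[i]]
    data.frame(pillar_id = colnames(Y)[i],
               F = tab[["F value"]][1],
               df_between = tab[["Df"]][1],
               df_within = tab[["Df"]][2],
               p = tab[["Pr(>F)"]][1],
               stringsAsFactors = FALSE)
  }))
  rownames(uni_df) <- NULL
  structure(list(
    pillai = pillai,
    univariate = uni_df,
    n = nrow(d), zones = levels(droplevels(d$zone)), fit = fit),
    class = "zonal_manova")
}

# complete-case region x pillar frame with zone factor; validates the
# MANOVA preconditions
manova_frame <- function(scores, registry) {
  check_regions_resolve(scores$region_id, registry)
  wide <- scores_wide(scores)
  complete <- stats::complete.cases(wide)
  wide <- wide[complete, , drop = FALSE]
  zone <- registry$zone[match(rownames(wide), registry$region_id)]
  zone <- droplevels(zone)
  if (nlevels(zone) < 2L) validation_error("need at least 2 zones with usable regions")
  small <- names(which(table(zone) < 2L))
  if (length(small)) {
    validation_error("zone(s) with fewer than 2 usable regions: ",
                     paste(small, collapse = ", "))
  }
  within_var <- vapply(colnames(wide), function(p) {
    sum(tapply(wide[, p], zone, function(v) sum((v - mean(v))^2)))
  }, numeric(1))
  if (all(within_var == 0)) {
    validation_error("zero within-zone variance in every pillar; F undefined")
  }
  data.frame(region_id = rownames(wide), zone = zone, wide,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.zonal_manova <- function(x, ...) {
  cat(sprintf("Zonal MANOVA: %d regions, %d zones (%s)\n",
              x$n, length(x$zones), paste(x$zones, collapse = ", ")))
  if (!is.null(x$pillai)) {
    cat(sprintf("  Pillai's trace = %.4f, approx F(%g, %g) = %.3f, p = %.4g\n",
                x$pillai$statistic, x$pillai$df[1], x$pillai$df[2],
                x$pillai$F, x$pillai$p))
  }
  for (i in seq_len(nrow(x$univariate))) {
    u <- x$univariate[i, ]
    cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.4g\n",
                u$pillar_id, u$df_between, u$df_within, u$F, u$p))
  }
  invisible(x)
}

#' Bonferroni pairwise post-hoc comparisons between zones
#'
#' For one pillar, compares every unordered pair of zones following the
#' omnibus test. The unadjusted p-value comes from the two-sided t
#' statistic built on the pooled within-zone mean square (the error term
#' of the one-way ANOVA, `df_within` degrees of freedom); the Bonferroni
#' family is the set of pairwise comparisons within the pillar, so
#' `p_adj = min(1, choose(k, 2) * p)` for `k` zones. The mean difference
#' is `mean(zone_a) - mean(zone_b)`: negative values mean `zone_a`
#' underperforms `zone_b`.
#'
#' Listwise exclusion matches [zonal_manova()]: regions missing any
#' pillar score are dropped before comparison, so post-hoc results refer
#' to the same sample as the omnibus test.
#'
#' @param scores a `pillar_scores` data.frame (all pillars; used for the
#'   listwise-complete sample).
#' @param registry region registry.
#' @param pillar pillar id to compare.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame of class `posthoc_table` with columns `pillar_id`,
#'   `zone_a`, `zone_b`, `mean_diff`, `p`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(scores, registry, pillar, alpha = 0.05) {
  d <- manova_frame(scores, registry)
  if (!pillar %in% names(d)) validation_error("unknown pillar: ", pillar)
  x <- d[[pillar]]
  g <- d$zone
  k <- nlevels(g)
  n_i <- tapply(x, g, length)
  m_i <- tapply(x, g, mean)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df_w <- length(x) - k
  msw <- ssw / df_w
  n_comp <- choose(k, 2)
  pairs <- utils::combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- m_i[[a]] - m_i[[b]]
    se <- sqrt(msw * (1 / n_i[[a]] + 1 / n_i[[b]]))
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df_w)
    data.frame(pillar_id = pillar, zone_a = a, zone_b = b,
               mean_diff = diff, p = p, p_adj = min(1, n_comp * p),
               significant = min(1, n_comp * p) < alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("posthoc_table", "data.frame")
  res
}

#' Univariate regression of MHU on WE
#'
#' Ordinary least squares fit of the maternal healthcare utilisation
#' pillar score on the women empowerment pillar score at region level,
#' `MHU = b * WE + a`. Regions missing either score are dropped.
#'
#' @param scores a `pillar_scores` data.frame containing both pillars.
#' @param registry region registry (used to attach zones to the
#'   scatter-plot data).
#' @param response response pillar id (default `"MHU"`).
#' @param predictor predictor pillar id (default `"WE"`).
#' @return object of class `spi_regression`: list with `intercept`,
#'   `slope`, `r_squared`, `n`, `data` (region, zone, predictor,
#'   response values, ready for a scatter plot), `response`, `predictor`
#'   and the underlying [stats::lm()] `fit`.
#' @export
fit_we_mhu_regression <- function(scores, registry, response = "MHU",
                                  predictor = "WE") {
  check_regions_resolve(scores$region_id, registry)
  wide <- scores_wide(scores)
  for (p in c(response, predictor)) {
    if (!p %in% colnames(wide)) validation_error("pillar not in scores: ", p)
  }
  keep <- !is.na(wide[, response]) & !is.na(wide[, predictor])
  if (sum(keep) < 3L) {
    validation_error("need at least 3 regions with defined scores for both pillars")
  }
  d <- data.frame(region_id = rownames(wide)[keep],
                  zone = as.character(
                    registry$zone[match(rownames(wide)[keep], registry$region_id)]),
                  x = wide[keep, predictor], y = wide[keep, response],
                  stringsAsFactors = FALSE)
  names(d)[3:4] <- c(predictor, response)
  if (stats::var(d[[predictor]]) == 0) {
    validation_error("zero variance in predictor '", predictor,
                     "'; slope undefined")
  }
  fit <- stats::lm(stats::reformulate(predictor, response), data = d)
  # R^2 as the squared sample correlation; a constant response has
  # nothing to explain, so 0 rather than the 0/0 of the summary.lm route
  r2 <- if (stats::var(d[[response]]) == 0) 0 else
    stats::cor(d[[predictor]], d[[response]])^2
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n = nrow(d), data = d,
                 response = response, predictor = predictor, fit = fit),
            class = "spi_regression")
}

#' @export
print.spi_regression <- function(x, ...) {
  cat(sprintf("%s = %.4f * %s + %.4f   (R^2 = %.3f, n = %d regions)\n",
              x$response, x$slope, x$predictor, x$intercept,
              x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.spi_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' External validation on a user-supplied factsheet table
#'
#' Some published quantities — the zonal F statistics, post-hoc mean
#' differences, the regression R-squared and the national quantile
#' shares — depend on the full survey factsheet, which is not
#' redistributed with the package. This harness reruns the full pipeline
#' (score, classify, favourability, MANOVA, post-hoc, regression) on an
#' indicator table the user has downloaded and prepared, returning all of
#' those quantities for side-by-side comparison with published values.
#'
#' @param table an [indicator_table()] built from the external factsheet.
#' @param registry matching region registry.
#' @param config a [pillar_config()] using the factsheet's indicator ids.
#' @param alpha significance level for post-hoc flags.
#' @return an [spi_analysis()] object.
#' @export
external_validation <- function(table, registry, config, alpha = 0.05) {
  spi_analysis(table, registry, config, alpha = alpha)
}
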