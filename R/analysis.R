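#' End-to-end zonal disparity analysis
#'
#' Convenience wrapper chaining the full pipeline: pillar scoring,
#' quantile classification, zonal favourability, zonal MANOVA with
#' per-pillar F tests, Bonferroni post-hoc comparisons for every pillar,
#' and — when both pillars are configured — the region-level regression
#' of MHU on WE.
#'
#' @param table an [indicator_table()].
#' @param registry region registry resolving every table region.
#' @param config a [pillar_config()] (default: the shipped three-pillar
#'   configuration).
#' @param cutpoints optional quantile cutpoints, see [assign_quantiles()].
#' @param alpha significance level for post-hoc flags (default 0.05).
#' @return object of class `spi_analysis`: list with `scores`,
#'   `assignments`, `favourability`, `occupancy`, `manova`, `posthoc`
#'   (all pillars stacked), `regression` (or `NULL`), plus the inputs'
#'   `registry` and `config`.
#' @examples
#' sim <- generate_survey(synthetic_config(seed = 42))
#' fit <- spi_analysis(sim$table, sim$registry,
#'                     synthetic_pillar_config(synthetic_config()))
#' print(fit)
#' @export
spi_analysis <- function(table, registry, config = default_pillar_config(),
                         cutpoints = NULL, alpha = 0.05) {
  scores <- score_all(table, config, registry)
  assignments <- assign_quantiles(scores, cutpoints)
  fav <- favourability(assignments, registry, names(config$pillars))
  mv <- zonal_manova(scores, registry)
  posthoc <- do.call(rbind, lapply(names(config$pillars), function(p) {
    bonferroni_posthoc(scores, registry, p, alpha)
  }))
  class(posthoc) <- c("posthoc_table", "data.frame")
  regression <- NULL
  if (all(c("MHU", "WE") %in% names(config$pillars))) {
    regression <- fit_we_mhu_regression(scores, registry)
  }
  structure(list(scores = scores, assignments = assignments,
                 favourability = fav,
                 occupancy = attr(fav, "occupancy"),
                 manova = mv, posthoc = posthoc, regression = regression,
                 registry = registry, config = config, alpha = alpha),
            class = "spi_analysis")
}

#' @export
print.spi_analysis <- function(x, ...) {
  n_regions <- length(unique(x$scores$region_id))
  cat(sprintf("SPI zonal disparity analysis: %d regions, %d pillars\n\n",
              n_regions, length(x$config$pillars)))
  print(x$favourability)
  cat("\n")
  print(x$manova)
  n_sig <- sum(x$posthoc$significant)
  cat(sprintf("\nPost-hoc: %d of %d pairwise comparisons significant at adjusted alpha %.2f\n",
              n_sig, nrow(x$posthoc), x$alpha))
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression)
  }
  invisible(x)
}

#' @export
summary.spi_analysis <- function(object, ...) {
  structure(list(analysis = object), class = "summary.spi_analysis")
}

#' @export
print.summary.spi_analysis <- function(x, ...) {
  a <- x$analysis
  print(a)
  cat("\nNational quantile occupancy (%):\n")
  print.data.frame(a$occupancy, row.names = FALSE)
  sig <- a$posthoc[a$posthoc$significant, , drop = FALSE]
  cat("\nSignificant pairwise differences (Bonferroni-adjusted):\n")
  if (nrow(sig)) {
    sig$mean_diff <- round_half_up(sig$mean_diff, 2)
    print.data.frame(sig, row.names = FALSE)
  } else cat("  none significant\n")
  invisible(x)
}

#' Scatter plot of the WE to MHU relationship
#'
#' Region-level scatter of the two pillar scores with the fitted
#' regression line, points coloured by zone (base graphics).
#'
#' @param x an `spi_analysis` with a fitted regression.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spi_analysis <- function(x, ...) {
  if (is.null(x$regression)) {
    validation_error("analysis has no fitted regression to plot")
  }
  r <- x$regression
  d <- r$data
  zones <- sort(unique(d$zone))
  cols <- grDevices::hcl.colors(max(3L, length(zones)), "Dark 3")[seq_along(zones)]
  graphics::plot(d[[r$predictor]], d[[r$response]],
                 col = cols[match(d$zone, zones)], pch = 19,
                 xlab = paste(r$predictor, "score"),
                 ylab = paste(r$response, "score"), ...)
  graphics::abline(r$fit, lwd = 2)
  graphics::legend("topleft", legend = zones, col = cols, pch = 19, bty = "n")
  graphics::mtext(sprintf("R² = %.3f (n = %d regions)", r$r_squared, r$n),
                  side = 3, line = 0.2, adj = 1, cex = 0.8)
  invisible(x)
}
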