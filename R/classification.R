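QUANTILE_LABELS <- c(Q1 = "poor", Q2 = "fair", Q3 = "good", Q4 = "excellent")

#' Assign regions to performance quantiles
#'
#' Classifies each region's pillar score into four performance classes,
#' Q1 (poor) to Q4 (excellent). When `cutpoints` is not supplied, the
#' three cutpoints are the 25th, 50th and 75th percentiles of the defined
#' scores of that pillar, computed with the linear-interpolation
#' convention of [stats::quantile()] type 7. Ties at a cutpoint go to the
#' lower quantile: Q1 is `score <= c25`, Q2 is `c25 < score <= c50`, Q3
#' is `c50 < score <= c75`, Q4 is `score > c75`. Regions with undefined
#' scores receive no assignment.
#'
#' @param scores a `pillar_scores` data.frame from [score_all()], or any
#'   data.frame with columns `region_id`, `pillar_id`, `score`.
#' @param cutpoints optional: three strictly ascending numbers applied
#'   verbatim to every pillar, or a named list of such vectors keyed by
#'   pillar id, as an escape hatch to reproduce any alternative binning.
#' @return a `data.frame` of class `quantile_assignment` with columns
#'   `region_id`, `pillar_id`, `quantile` (`"Q1"`..`"Q4"`) and `label`
#'   (`poor`, `fair`, `good`, `excellent`); regions with undefined scores
#'   are omitted.
#' @export
assign_quantiles <- function(scores, cutpoints = NULL) {
  stopifnot(all(c("region_id", "pillar_id", "score") %in% names(scores)))
  out <- list()
  for (p in unique(scores$pillar_id)) {
    sub <- scores[scores$pillar_id == p & !is.na(scores$score), , drop = FALSE]
    cp <- cutpoints
    if (is.list(cp)) cp <- cp[[p]]
    if (is.null(cp)) {
      if (nrow(sub) < 4L) {
        validation_error(sprintf(
          "pillar '%s': need at least 4 defined scores to estimate cutpoints (have %d)",
          p, nrow(sub)))
      }
      cp <- unname(stats::quantile(sub$score, c(0.25, 0.5, 0.75), type = 7))
    } else {
      if (length(cp) != 3L || is.unsorted(cp, strictly = TRUE)) {
        validation_error(sprintf(
          "pillar '%s': cutpoints must be three strictly ascending numbers", p))
      }
    }
    q <- quantile_bin(sub$score, cp)
    out[[p]] <- data.frame(region_id = sub$region_id, pillar_id = p,
                           quantile = paste0("Q", q),
                           label = unname(QUANTILE_LABELS[q]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("quantile_assignment", "data.frame")
  res
}

# half-open binning with ties to the lower bin: bin k iff score > cp[k-1]
# and score <= cp[k]
quantile_bin <- function(x, cp) {
  findInterval(x, cp, left.open = TRUE) + 1L
}

#' Zonal favourability score from quantile counts
#'
#' The favourability score of a zone for a pillar is the percentage of
#' the zone's regions whose pillar score falls in the upper two
#' performance quantiles (Q3 or Q4), rounded half away from zero to one
#' decimal:
#' \deqn{100 \times n_{Q3+Q4} / n_{total}}
#'
#' @param n_q34 count of the zone's regions in Q3 or Q4.
#' @param n_total total count of regions in the zone (regions with
#'   undefined pillar scores still count here: they are regions in the
#'   zone, just never favourable).
#' @return the favourability percentage, one decimal.
#' @examples
#' favourability_score(15, 17)  # 88.2
#' favourability_score(5, 16)   # 31.3 (31.25 rounds half away from zero)
#' @export
favourability_score <- function(n_q34, n_total) {
  stopifnot(is.numeric(n_q34), is.numeric(n_total))
  if (any(n_total < 1)) validation_error("zone has zero regions")
  if (any(n_q34 < 0 | n_q34 > n_total)) {
    validation_error("n_q34 must lie in [0, n_total]")
  }
  round_half_up(100 * n_q34 / n_total, 1)
}

#' Favourability table across zones and pillars
#'
#' Builds the zone x pillar favourability table: for each zone and
#' pillar, the total number of regions in the zone, the number of those
#' in Q3 or Q4, and the favourability percentage. National quantile
#' occupancy shares per pillar are attached as attribute `occupancy`
#' (also available via [quantile_occupancy()]).
#'
#' @param assignments a `quantile_assignment` data.frame from
#'   [assign_quantiles()].
#' @param registry region registry resolving every assigned region.
#' @param pillars pillar ids to tabulate (default: all present).
#' @return a `data.frame` of class `favourability_table` with columns
#'   `zone`, `pillar_id`, `n_total`, `n_q34`, `score`.
#' @export
favourability <- function(assignments, registry,
                          pillars = unique(assignments$pillar_id)) {
  check_regions_resolve(assignments$region_id, registry)
  zones <- levels(registry$zone)[table(registry$zone) > 0]
  if (!length(zones)) validation_error("registry has no zones")
  zone_of <- stats::setNames(as.character(registry$zone), registry$region_id)
  rows <- list()
  for (z in zones) {
    in_zone <- registry$region_id[registry$zone == z]
    for (p in pillars) {
      a <- assignments[assignments$pillar_id == p &
                         assignments$region_id %in% in_zone, , drop = FALSE]
      n_q34 <- sum(a$quantile %in% c("Q3", "Q4"))
      rows[[paste(z, p)]] <- data.frame(
        zone = z, pillar_id = p, n_total = length(in_zone), n_q34 = n_q34,
        score = favourability_score(n_q34, length(in_zone)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "occupancy") <- quantile_occupancy(assignments, pillars)
  class(res) <- c("favourability_table", "data.frame")
  res
}

#' National quantile occupancy shares
#'
#' Share of all assigned regions falling in each quantile, per pillar, as
#' percentages rounded to two decimals (the convention used when quoting
#' shares such as "26.76% of the nation fall in the fourth quantile").
#'
#' @param assignments a `quantile_assignment` data.frame.
#' @param pillars pillar ids to tabulate (default: all present).
#' @return data.frame with columns `pillar_id`, `quantile`, `n`,
#'   `share` (percentage).
#' @export
quantile_occupancy <- function(assignments,
                               pillars = unique(assignments$pillar_id)) {
  rows <- list()
  for (p in pillars) {
    a <- assignments[assignments$pillar_id == p, , drop = FALSE]
    tab <- table(factor(a$quantile, levels = paste0("Q", 1:4)))
    rows[[p]] <- data.frame(
      pillar_id = p, quantile = names(tab), n = as.integer(tab),
      share = round_half_up(100 * as.integer(tab) / nrow(a), 2),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @export
print.favourability_table <- function(x, digits = 1, ...) {
  cat("Zonal favourability (% of zone regions in Q3/Q4)\n")
  wide <- favourability_wide(x)
  print.data.frame(wide, row.names = FALSE)
  invisible(x)
}

# one row per zone mirroring the published table layout:
# zone, n_total, n_q34 per pillar, favourability per pillar
favourability_wide <- function(fav) {
  pillars <- unique(fav$pillar_id)
  zones <- unique(fav$zone)
  out <- data.frame(zone = zones, stringsAsFactors = FALSE)
  out$n_total <- fav$n_total[match(zones, fav$zone)]
  for (p in pillars) {
    sub <- fav[fav$pillar_id == p, ]
    out[[paste0("n_q34_", p)]] <- sub$n_q34[match(zones, sub$zone)]
  }
  for (p in pillars) {
    sub <- fav[fav$pillar_id == p, ]
    out[[paste0("fav_", p)]] <- sub$score[match(zones, sub$zone)]
  }
  out
}

#' Write quantile assignments to CSV
#'
#' @param assignments a `quantile_assignment` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write_csv_strict(as.data.frame(assignments), path)
}

#' Write the favourability table to CSV (published-table layout)
#'
#' One row per zone: `zone,n_total,n_q34_<pillar>...,fav_<pillar>...`.
#' A tidy long-format companion (zone, pillar_id, n_total, n_q34, score),
#' suitable for external choropleth tools, is written alongside when
#' `tidy_path` is given.
#'
#' @param fav a `favourability_table`.
#' @param path output path for the wide layout.
#' @param tidy_path optional output path for the tidy layout.
#' @return `path`, invisibly.
#' @export
write_favourability <- function(fav, path, tidy_path = NULL) {
  write_csv_strict(favourability_wide(fav), path)
  if (!is.null(tidy_path)) write_csv_strict(as.data.frame(fav), tidy_path)
  invisible(path)
}
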