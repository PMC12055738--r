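#' Dimension score with the missing-value denominator rule
#'
#' The dimension score is the unweighted average of the dimension's
#' indicator values, computed under the rule that missing indicators
#' contribute zero to the numerator and are excluded from the
#' denominator: the score is the mean of the non-missing values. With a
#' single non-missing indicator the score equals that value. When every
#' indicator is missing the score is undefined (`NA`), never coerced to
#' zero — an all-missing dimension carries no information, and zero would
#' read as worst possible performance.
#'
#' @param values numeric vector of indicator values in [0, 100]; `NA`
#'   marks missing.
#' @return list with `score` (numeric or `NA`) and `n_effective` (count
#'   of non-missing indicators).
#' @examples
#' dimension_score(c(80, NA, 60))  # score 70, n_effective 2
#' @export
dimension_score <- function(values) {
  if (!length(values)) validation_error("dimension has no indicators (misconfigured)")
  n_eff <- sum(!is.na(values))
  score <- if (n_eff == 0L) NA_real_ else sum(values, na.rm = TRUE) / n_eff
  list(score = score, n_effective = n_eff)
}

#' Pillar score from dimension scores
#'
#' Aggregates dimension scores into a pillar score. With all weights
#' equal to 1 this is the mean of the defined dimension scores, using the
#' same excluded-from-denominator rule as [dimension_score()] for
#' undefined dimensions. With general nonnegative weights the score is
#' the weighted mean `sum(w * d) / sum(w)` over the defined dimensions,
#' which reduces to the unweighted rule when all weights are equal.
#'
#' @param dim_scores numeric vector of dimension scores; `NA` marks an
#'   undefined dimension.
#' @param weights nonnegative numeric vector, recycled scalar allowed
#'   (default 1); at least one weight must be positive.
#' @param n_effective optional integer vector of per-dimension indicator
#'   counts (defaults to 1 per defined dimension) so the pillar can
#'   report how many indicators contributed.
#' @return list with `score` (numeric or `NA`) and `n_effective`.
#' @examples
#' pillar_score(c(70, 90))$score            # 80
#' pillar_score(c(70, NA))$score            # 70
#' pillar_score(c(60, 90), c(2, 1))$score   # 70
#' @export
pillar_score <- function(dim_scores, weights = 1, n_effective = NULL) {
  if (!length(dim_scores)) validation_error("pillar has no dimensions (misconfigured)")
  weights <- rep_len(weights, length(dim_scores))
  if (any(weights < 0)) validation_error("dimension weights must be nonnegative")
  if (all(weights == 0)) validation_error("all dimension weights are zero")
  if (is.null(n_effective)) n_effective <- as.integer(!is.na(dim_scores))
  defined <- !is.na(dim_scores) & weights > 0
  if (!any(defined)) {
    return(list(score = NA_real_, n_effective = 0L))
  }
  score <- sum(weights[defined] * dim_scores[defined]) / sum(weights[defined])
  list(score = score, n_effective = as.integer(sum(n_effective[defined])))
}

#' Score every region on every pillar
#'
#' Runs the indicator -> dimension -> pillar aggregation for each region
#' and pillar in the configuration. Scores are kept at full floating
#' precision; rounding happens only at reporting time.
#'
#' @param table an [indicator_table()].
#' @param config a [pillar_config()]; every configured indicator must be
#'   a column of `table`.
#' @param registry optional region registry; when supplied, every region
#'   in `table` must resolve against it.
#' @return a `data.frame` of class `pillar_scores` with columns
#'   `region_id`, `pillar_id`, `score` (`NA` when undefined) and
#'   `n_effective`, one row per (region, pillar), regions in table order
#'   and pillars in configuration order.
#' @export
score_all <- function(table, config, registry = NULL) {
  stopifnot(inherits(table, "indicator_table"), inherits(config, "pillar_config"))
  absent <- setdiff(config_indicators(config), colnames(table))
  if (length(absent)) {
    validation_error("config references indicator(s) absent from the table: ",
                     paste(absent, collapse = ", "))
  }
  if (!is.null(registry)) check_regions_resolve(rownames(table), registry)
  values <- apply_polarity(unclass(table), config)

  out <- list()
  for (p in names(config$pillars)) {
    dims <- config$pillars[[p]]
    dim_mat <- vapply(dims, function(d) {
      vapply(seq_len(nrow(values)), function(r) {
        dimension_score(values[r, d$indicators])$score
      }, numeric(1))
    }, numeric(nrow(values)))
    dim_mat <- matrix(dim_mat, nrow = nrow(values))
    neff_mat <- vapply(dims, function(d) {
      rowSums(!is.na(values[, d$indicators, drop = FALSE]))
    }, numeric(nrow(values)))
    neff_mat <- matrix(neff_mat, nrow = nrow(values))
    w <- vapply(dims, `[[`, numeric(1), "weight")
    rows <- lapply(seq_len(nrow(values)), function(r) {
      pillar_score(dim_mat[r, ], w, n_effective = neff_mat[r, ])
    })
    out[[p]] <- data.frame(
      region_id = rownames(values),
      pillar_id = p,
      score = vapply(rows, `[[`, numeric(1), "score"),
      n_effective = vapply(rows, `[[`, integer(1), "n_effective"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pillar_scores", "data.frame")
  res
}

#' Write pillar scores to long-format CSV
#'
#' Columns `region_id,pillar_id,score,n_effective`; undefined scores are
#' written as empty cells; values keep full precision (default 15
#' significant digits, enough for an exact read-back round trip).
#'
#' @param scores a `pillar_scores` data.frame from [score_all()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (!nrow(scores)) validation_error("scores must be nonempty")
  out <- scores
  out$score <- ifelse(is.na(out$score), "",
                      formatC(out$score, digits = 15, format = "g"))
  write_csv_strict(as.data.frame(out), path)
}

#' Read pillar scores written by [write_scores()]
#'
#' @param path path to the scores CSV.
#' @return a `pillar_scores` data.frame.
#' @export
read_scores <- function(path) {
  df <- read_csv_strict(path)
  df$score <- suppressWarnings(as.numeric(df$score))
  df$n_effective <- as.integer(df$n_effective)
  class(df) <- c("pillar_scores", "data.frame")
  df
}

# wide region x pillar score matrix from a long pillar_scores frame
scores_wide <- function(scores) {
  pillars <- unique(scores$pillar_id)
  regions <- unique(scores$region_id)
  m <- matrix(NA_real_, length(regions), length(pillars),
              dimnames = list(regions, pillars))
  m[cbind(match(scores$region_id, regions),
          match(scores$pillar_id, pillars))] <- scores$score
  m
}
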