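#' Construct an indicator table
#'
#' An indicator table holds percentage-valued survey indicators (one row
#' per region, one column per indicator) on the closed interval [0, 100],
#' with `NA` marking missing cells. It is the raw input to SPI scoring.
#'
#' @param values numeric matrix, regions x indicators, with rownames set
#'   to region ids and colnames to indicator ids; `NA` encodes missing.
#' @param survey_round text tag for the survey round the values belong to.
#' @return an object of class `indicator_table`: the matrix plus a
#'   `survey_round` attribute.
#' @export
indicator_table <- function(values, survey_round = "NFHS-5") {
  if (!is.matrix(values) || !is.numeric(values)) {
    validation_error("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    validation_error("values must carry region ids as rownames and indicator ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    validation_error("duplicate region_id in indicator table")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  if (nrow(bad)) {
    validation_error(sprintf(
      "indicator value out of [0, 100] at region '%s', indicator '%s': %g",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, 1], bad[1, 2]]))
  }
  structure(values, survey_round = survey_round, class = c("indicator_table", "matrix"))
}

#' Read an indicator table from wide CSV
#'
#' Expects a header row, a first column `region_id`, and one column per
#' indicator. Cells equal to the empty string or any of `missing_tokens`
#' are treated as missing; all other cells must parse as numbers in
#' [0, 100].
#'
#' @param path path to the CSV file.
#' @param missing_tokens character vector of cell values treated as
#'   missing in addition to the empty string. Factsheet exports vary, so
#'   `"NA"` and `"."` are accepted by default.
#' @param survey_round survey round tag stored on the result.
#' @return an [indicator_table()].
#' @export
read_indicator_table <- function(path, missing_tokens = c("NA", "."),
                                 survey_round = "NFHS-5") {
  df <- read_csv_strict(path)
  if (names(df)[1] != "region_id") {
    validation_error("first column of an indicator table must be region_id")
  }
  region_id <- as.character(df$region_id)
  ind_cols <- names(df)[-1]
  if (!length(ind_cols)) validation_error("indicator table has no indicator columns")
  m <- matrix(NA_real_, nrow(df), length(ind_cols),
              dimnames = list(region_id, ind_cols))
  for (j in seq_along(ind_cols)) {
    raw <- trimws(as.character(df[[ind_cols[j]]]))
    is_missing <- raw == "" | raw %in% missing_tokens
    parsed <- suppressWarnings(as.numeric(raw))
    bad_parse <- which(!is_missing & is.na(parsed))
    if (length(bad_parse)) {
      validation_error(sprintf(
        "cannot parse cell (region '%s', indicator '%s'): '%s'",
        region_id[bad_parse[1]], ind_cols[j], raw[bad_parse[1]]))
    }
    parsed[is_missing] <- NA_real_
    m[, j] <- parsed
  }
  indicator_table(m, survey_round = survey_round)
}

#' Write an indicator table to wide CSV
#'
#' Missing cells are written as empty strings; values keep full precision.
#'
#' @param table an [indicator_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  df <- data.frame(region_id = rownames(table),
                   as.data.frame(unclass(table)[, , drop = FALSE]),
                   check.names = FALSE)
  write_csv_strict(df, path)
}

#' Missingness mask of an indicator table
#'
#' @param table an [indicator_table()].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) {
  is.na(unclass(table))
}

#' @export
print.indicator_table <- function(x, ...) {
  cat(sprintf("Indicator table (%s): %d regions x %d indicators, %d missing cells\n",
              attr(x, "survey_round"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
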