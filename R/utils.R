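#' Zone codes used throughout the package
#'
#' The six administrative zones of the Indian Zonal Council system:
#' Central (C), East (E), North (N), Northeast (NE), South (S), West (W).
#'
#' @format Character vector of length six.
#' @export
ZONES <- c("C", "E", "N", "NE", "S", "W")

#' Default pillar identifiers
#'
#' MHU = maternal healthcare utilisation, WE = women empowerment,
#' DC = delivery care.
#'
#' @format Character vector of length three.
#' @export
PILLARS <- c("MHU", "WE", "DC")

#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero, the
#' convention used for all reported percentages and mean differences
#' (e.g. 31.25 -> 31.3, -19.415 -> -19.42). This differs from base
#' [round()], which rounds halves to the nearest even digit.
#'
#' Values are first rounded to 8 decimals to cancel binary representation
#' error, so 1941.4999... stays below the half boundary while an exact
#' 312.5 crosses it.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 1).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(31.25, 56.25, 93.75))      # 31.3 56.3 93.8
#' round_half_up(-19.414999, 2)               # -19.41
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  z <- round(abs(x) * scale, 8)
  sign(x) * floor(z + 0.5) / scale
}

# stop() with a consistent condition class so the CLI can map validation
# failures to a dedicated exit code
validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("spizonal_validation_error",
                                             "error", "condition")))
}

# read a CSV in the strict dialect used by all package artifacts
read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("spizonal_io_error", "error", "condition")))
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = character(0))
}

write_csv_strict <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
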