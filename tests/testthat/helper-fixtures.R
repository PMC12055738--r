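# In-code fixtures shared across test files. All synthetic.

# registry with n_per_zone regions in each named zone
toy_registry <- function(n_per_zone) {
  rows <- lapply(names(n_per_zone), function(z) {
    n <- n_per_zone[[z]]
    data.frame(region_id = sprintf("u_%s%d", z, seq_len(n)),
               state = sprintf("%s%d", z, seq_len(n)),
               zone = z, residence = "urban", stringsAsFactors = FALSE)
  })
  validate_registry(do.call(rbind, rows))
}

# long pillar_scores frame from a named vector of scores for one pillar
toy_scores <- function(values, pillar = "MHU") {
  structure(data.frame(region_id = names(values), pillar_id = pillar,
                       score = unname(values),
                       n_effective = ifelse(is.na(values), 0L, 1L),
                       stringsAsFactors = FALSE),
            class = c("pillar_scores", "data.frame"))
}

# indicator_table from a plain matrix
toy_table <- function(m, regions = NULL, indicators = NULL) {
  if (!is.null(regions)) rownames(m) <- regions
  if (!is.null(indicators)) colnames(m) <- indicators
  indicator_table(m, survey_round = "synthetic")
}

# one single-indicator dimension per indicator, all weight 1
flat_config <- function(pillars) {
  pillar_config(lapply(pillars, function(ids) {
    lapply(ids, function(i) list(id = i, indicators = i, weight = 1))
  }))
}

# write a CSV fixture into a temp file, return its path
temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# type-7 percentile computed from first principles (sort + linear
# interpolation at h = (n-1)p), independent of stats::quantile
manual_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# brute-force sort-and-split quantile oracle: bin each score against
# manually interpolated cutpoints with ties to the lower bin
oracle_quantile_bins <- function(scores) {
  cps <- vapply(c(0.25, 0.5, 0.75), function(p) manual_percentile(scores, p),
                numeric(1))
  vapply(scores, function(s) 1L + sum(s > cps), integer(1))
}

# hand one-way ANOVA from sums of squares
oracle_oneway_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  list(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2)
}

# decimal-string rounding oracle, half away from zero
oracle_round_string <- function(x, digits) {
  s <- format(abs(x), nsmall = digits + 1, scientific = FALSE, digits = 15)
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  frac <- parts[2]
  keep <- as.numeric(paste0(parts[1], substr(frac, 1, digits)))
  next_digit <- as.numeric(substr(frac, digits + 1, digits + 1))
  if (next_digit >= 5) keep <- keep + 1
  sign(x) * keep / 10^digits
}
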