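#' Render a Markdown report from pipeline artifacts
#'
#' Pure presentation layer: reads the CSV artifacts written by
#' [run_pipeline()] and formats them; no statistic is recomputed.
#' The report contains the zonal favourability table (published-table
#' layout), the national quantile occupancy shares, the MANOVA summary,
#' the post-hoc table restricted to significant pairs (starred `*` for
#' adjusted p < .05, `**` for adjusted p < .001, with an explicit "none
#' significant" line when empty), and the regression summary.
#' Reporting precision: percentages 1 decimal, mean differences 2
#' decimals, F statistics 3 decimals.
#'
#' @param artifact_dir directory containing the pipeline CSVs.
#' @param path output path for the report (default
#'   `artifact_dir/report.md`).
#' @return the report path, invisibly.
#' @export
render_report <- function(artifact_dir, path = file.path(artifact_dir, "report.md")) {
  need <- function(name, stage) {
    f <- file.path(artifact_dir, name)
    if (!file.exists(f)) {
      stop(errorCondition(
        sprintf("missing artifact '%s'; rerun the '%s' stage", name, stage),
        class = c("spizonal_io_error", "error", "condition")))
    }
    read_csv_strict(f)
  }
  fav <- need("favourability.csv", "favourability")
  occ <- need("occupancy.csv", "classify")
  mv <- need("manova.csv", "infer")
  ph <- need("posthoc.csv", "infer")

  fmt1 <- function(x) formatC(round_half_up(as.numeric(x), 1), format = "f", digits = 1)
  fmt2 <- function(x) formatC(round_half_up(as.numeric(x), 2), format = "f", digits = 2)
  fmt3 <- function(x) formatC(round_half_up(as.numeric(x), 3), format = "f", digits = 3)
  md_table <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body)
  }

  lines <- c("# Zonal disparity report", "")

  lines <- c(lines, "## Favourability of zones", "",
             "Percentage of each zone's regions in the upper two quantiles (Q3/Q4), per pillar.", "")
  fav_fmt <- fav
  for (cl in grep("^fav_", names(fav_fmt))) fav_fmt[[cl]] <- fmt1(fav_fmt[[cl]])
  lines <- c(lines, md_table(fav_fmt), "")

  lines <- c(lines, "## National quantile occupancy", "")
  occ$share <- fmt2(occ$share)
  lines <- c(lines, md_table(occ), "")

  lines <- c(lines, "## Zonal MANOVA", "")
  mv_fmt <- data.frame(pillar = mv$pillar_id,
                       F = fmt3(mv$F),
                       df = sprintf("(%s, %s)", mv$df_between, mv$df_within),
                       p = fmt3(mv$p), stringsAsFactors = FALSE)
  lines <- c(lines, md_table(mv_fmt), "")
  if ("pillai" %in% names(mv) && nzchar(mv$pillai[1])) {
    lines <- c(lines, sprintf("Pillai's trace = %s (p = %s)",
                              fmt3(mv$pillai[1]), fmt3(mv$pillai_p[1])), "")
  }

  lines <- c(lines, "## Significant pairwise zone differences (Bonferroni)", "")
  sig <- ph[ph$significant %in% c("TRUE", TRUE), , drop = FALSE]
  if (nrow(sig)) {
    stars <- ifelse(as.numeric(sig$p_adj) < 0.001, "**", "*")
    sig_fmt <- data.frame(pillar = sig$pillar_id, zones = paste(sig$zone_a, "vs", sig$zone_b),
                          mean_diff = paste0(fmt2(sig$mean_diff), stars),
                          stringsAsFactors = FALSE)
    lines <- c(lines, md_table(sig_fmt), "",
               "`*` adjusted p < .05; `**` adjusted p < .001", "")
  } else {
    lines <- c(lines, "none significant", "")
  }

  reg_path <- file.path(artifact_dir, "regression.csv")
  if (file.exists(reg_path)) {
    reg <- read_csv_strict(reg_path)
    lines <- c(lines, "## Regression of MHU on WE", "",
               sprintf("MHU = %s x WE + %s, R² = %s, n = %s regions",
                       fmt3(reg$slope), fmt2(reg$intercept),
                       fmt3(reg$r_squared), reg$n), "")
  }

  writeLines(lines, path)
  invisible(path)
}
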