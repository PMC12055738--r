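#' Run the analysis pipeline from command-line style arguments
#'
#' Thin orchestration layer behind the shipped command-line script.
#' Subcommands: `simulate`, `score`, `classify`, `favourability`,
#' `infer`, `regress`, `report`, and `all` (which chains
#' simulate-or-load, score, classify, favourability, infer, regress,
#' report in pipeline order). Flags: `--registry`, `--indicators`,
#' `--pillar-config`, `--simulate-config`, `--cutpoints` (three
#' comma-separated numbers), `--alpha`, `--seed`, `--out`,
#' `--log-level` (`quiet`/`info`).
#'
#' All outputs are CSV files in the `--out` directory; reruns with the
#' same inputs and seed are byte-identical. Stages that need no
#' randomness ignore the seed.
#'
#' @param argv character vector of arguments (as from
#'   [commandArgs](trailingOnly = TRUE)).
#' @return integer exit status, invisibly: 0 on success, 2 for a missing
#'   input file, 3 for a validation failure, 1 otherwise.
#' @export
run_pipeline <- function(argv) {
  status <- tryCatch({
    run_pipeline_inner(argv)
    0L
  },
  spizonal_io_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  spizonal_validation_error = function(e) { message("error: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_args <- function(argv) {
  if (!length(argv)) validation_error("no subcommand given")
  cmd <- argv[1]
  valid <- c("simulate", "score", "classify", "favourability", "infer",
             "regress", "report", "all")
  if (!cmd %in% valid) {
    validation_error("unknown subcommand '", cmd, "'; expected one of: ",
                     paste(valid, collapse = ", "))
  }
  flags <- list()
  i <- 2L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) validation_error("expected a --flag, got '", key, "'")
    if (i + 1L > length(argv)) validation_error("flag ", key, " needs a value")
    flags[[substring(key, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  list(cmd = cmd, flags = flags)
}

run_pipeline_inner <- function(argv) {
  parsed <- parse_cli_args(argv)
  cmd <- parsed$cmd
  fl <- parsed$flags
  out_dir <- fl$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_level <- fl[["log-level"]] %||% "info"
  say <- function(...) if (log_level != "quiet") message("[spizonal] ", sprintf(...))
  alpha <- as.numeric(fl$alpha %||% "0.05")
  seed <- as.integer(fl$seed %||% "1")
  cutpoints <- if (!is.null(fl$cutpoints)) {
    as.numeric(strsplit(fl$cutpoints, ",")[[1]])
  } else NULL

  art <- function(name) file.path(out_dir, name)
  say("subcommand %s, output %s, seed %d", cmd, out_dir, seed)

  if (cmd %in% c("simulate", "all")) {
    scfg <- if (!is.null(fl[["simulate-config"]])) {
      read_synthetic_config(fl[["simulate-config"]], seed = seed)
    } else synthetic_config(seed = seed)
    sim <- generate_survey(scfg)
    write_region_registry(sim$registry, art("registry.csv"))
    write_indicator_table(sim$table, art("indicators.csv"))
    pcfg_sim <- synthetic_pillar_config(scfg)
    yaml::write_yaml(pillar_config_to_list(pcfg_sim), art("pillar_config.yaml"))
    say("simulated %d regions x %d indicators (%d values clipped)",
        nrow(sim$table), ncol(sim$table), sim$n_clipped)
  }

  load_inputs <- function() {
    reg_path <- fl$registry %||% art("registry.csv")
    ind_path <- fl$indicators %||% art("indicators.csv")
    cfg_path <- fl[["pillar-config"]] %||% art("pillar_config.yaml")
    list(registry = read_region_registry(reg_path),
         table = read_indicator_table(ind_path),
         config = read_pillar_config(cfg_path))
  }

  if (cmd %in% c("score", "all")) {
    inp <- load_inputs()
    scores <- score_all(inp$table, inp$config, inp$registry)
    write_scores(scores, art("scores.csv"))
    say("scored %d regions on %d pillars", length(unique(scores$region_id)),
        length(unique(scores$pillar_id)))
  }

  if (cmd %in% c("classify", "favourability", "all")) {
    reg <- read_region_registry(fl$registry %||% art("registry.csv"))
    scores <- read_scores(art("scores.csv"))
    asn <- assign_quantiles(scores, cutpoints)
    write_assignments(asn, art("assignments.csv"))
    fav <- favourability(asn, reg)
    write_favourability(fav, art("favourability.csv"),
                        tidy_path = art("favourability_tidy.csv"))
    write_csv_strict(attr(fav, "occupancy"), art("occupancy.csv"))
    say("classified %d (region, pillar) scores; %d favourability rows",
        nrow(asn), nrow(fav))
  }

  if (cmd %in% c("infer", "all")) {
    reg <- read_region_registry(fl$registry %||% art("registry.csv"))
    scores <- read_scores(art("scores.csv"))
    mv <- zonal_manova(scores, reg)
    mv_df <- mv$univariate
    mv_df$pillai <- mv$pillai$statistic %||% NA_real_
    mv_df$pillai_p <- mv$pillai$p %||% NA_real_
    write_csv_strict(mv_df, art("manova.csv"))
    ph <- do.call(rbind, lapply(unique(scores$pillar_id), function(p) {
      bonferroni_posthoc(scores, reg, p, alpha)
    }))
    write_csv_strict(as.data.frame(ph), art("posthoc.csv"))
    say("MANOVA on %d regions; %d post-hoc rows", mv$n, nrow(ph))
  }

  if (cmd %in% c("regress", "all")) {
    reg <- read_region_registry(fl$registry %||% art("registry.csv"))
    scores <- read_scores(art("scores.csv"))
    if (all(c("MHU", "WE") %in% scores$pillar_id)) {
      r <- fit_we_mhu_regression(scores, reg)
      write_csv_strict(data.frame(intercept = r$intercept, slope = r$slope,
                                  r_squared = r$r_squared, n = r$n),
                       art("regression.csv"))
      write_csv_strict(r$data, art("regression_scatter.csv"))
      say("regression: slope %.4f, R^2 %.3f", r$slope, r$r_squared)
    } else say("skipping regression: MHU/WE pillars not both present")
  }

  if (cmd %in% c("report", "all")) {
    path <- render_report(out_dir)
    say("report written to %s", path)
  }
  invisible(NULL)
}

# serialize a pillar_config back to the YAML structure read_pillar_config
# accepts
pillar_config_to_list <- function(config) {
  pillars <- lapply(config$pillars, function(dims) {
    list(dimensions = lapply(dims, function(d) {
      list(id = d$id, indicators = as.list(d$indicators), weight = d$weight)
    }))
  })
  out <- list(pillars = pillars)
  if (length(config$polarity)) out$polarity <- as.list(config$polarity)
  out
}

#' Read a synthetic-survey configuration from YAML
#'
#' Recognised keys: `zone_sizes` (zone -> count), `pillar_spec`
#' (pillar -> indicator count), `zone_means` (zone -> pillar -> mean),
#' `indicator_sd`, `region_sd`, `missing_rate`, `seed`. Omitted keys
#' fall back to the [synthetic_config()] defaults.
#'
#' @param path path to the YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("spizonal_io_error", "error", "condition")))
  }
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$zone_sizes)) args$zone_sizes <- unlist(y$zone_sizes)
  if (!is.null(y$pillar_spec)) args$pillar_spec <- unlist(y$pillar_spec)
  if (!is.null(y$zone_means)) {
    zs <- args$zone_sizes %||% c(C = 6, E = 8, N = 17, NE = 16, S = 16, W = 8)
    ps <- args$pillar_spec %||% c(MHU = 8, WE = 7, DC = 7)
    m <- matrix(NA_real_, length(zs), length(ps),
                dimnames = list(names(zs), names(ps)))
    for (z in names(y$zone_means)) for (p in names(y$zone_means[[z]])) {
      m[z, p] <- y$zone_means[[z]][[p]]
    }
    if (anyNA(m)) validation_error("zone_means in config must cover every (zone, pillar)")
    args$zone_means <- m
  }
  for (k in c("indicator_sd", "region_sd", "missing_rate")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  args$seed <- seed %||% y$seed %||% 1L
  do.call(synthetic_config, args)
}
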