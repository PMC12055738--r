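#' Configuration for the synthetic survey generator
#'
#' Describes an NFHS-like study layout: regions partitioned into six
#' zones (default sizes 6/8/17/16/16/8, total 71), 22 percentage-valued
#' indicators split across three pillars, zone-by-pillar mean levels,
#' indicator-level offsets, region-level Gaussian noise, and optional
#' completely-at-random missingness.
#'
#' The generative model for region r in zone z and indicator j of pillar
#' p is
#' \deqn{v_{rj} = clip(\mu_{zp} + o_j + \epsilon_{rj},\ 0,\ 100)}
#' where the indicator offset `o_j ~ N(0, indicator_sd^2)` is drawn once
#' per indicator, the noise `eps_rj ~ N(0, region_sd^2)` independently
#' per cell, and cells are then masked missing independently with
#' probability `missing_rate`. Clipping events are counted and reported
#' so calibration runs can keep means away from the bounds.
#'
#' @param zone_sizes named integer vector, regions per zone (names from
#'   [ZONES]).
#' @param pillar_spec named integer vector, indicators per pillar.
#' @param zone_means numeric matrix `length(zone_sizes)` x
#'   `length(pillar_spec)` (dimnames zone x pillar), mean level in
#'   [0, 100] for each zone and pillar.
#' @param indicator_sd spread (sd) of the per-indicator offsets, > 0
#'   allowed to be 0 for noiseless checks.
#' @param region_sd sd of the per-cell noise; 0 allowed for noiseless
#'   checks.
#' @param missing_rate probability a cell is masked missing, in [0, 1).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(zone_sizes = c(C = 6, E = 8, N = 17, NE = 16,
                                            S = 16, W = 8),
                             pillar_spec = c(MHU = 8, WE = 7, DC = 7),
                             zone_means = default_zone_means(
                               names(zone_sizes), names(pillar_spec)),
                             indicator_sd = 5,
                             region_sd = 8,
                             missing_rate = 0,
                             seed = 1L) {
  if (is.null(names(zone_sizes)) || !all(names(zone_sizes) %in% ZONES)) {
    validation_error("zone_sizes must be named with zone codes from: ",
                     paste(ZONES, collapse = ", "))
  }
  if (any(zone_sizes < 1)) validation_error("every zone needs at least 1 region")
  if (is.null(names(pillar_spec)) || any(pillar_spec < 1)) {
    validation_error("pillar_spec must be a named vector of positive counts")
  }
  zone_means <- as.matrix(zone_means)
  if (!identical(rownames(zone_means), names(zone_sizes)) ||
      !identical(colnames(zone_means), names(pillar_spec))) {
    validation_error("zone_means must have rownames = zones and colnames = pillars")
  }
  if (any(zone_means < 0 | zone_means > 100)) {
    validation_error("zone_means must lie in [0, 100]")
  }
  if (indicator_sd < 0 || region_sd < 0) validation_error("sds must be nonnegative")
  if (missing_rate < 0 || missing_rate >= 1) {
    validation_error("missing_rate must lie in [0, 1)")
  }
  structure(list(zone_sizes = zone_sizes, pillar_spec = pillar_spec,
                 zone_means = zone_means, indicator_sd = indicator_sd,
                 region_sd = region_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default zone-by-pillar mean levels
#'
#' Plausible percentage levels reflecting the qualitative zonal ordering
#' seen in Indian maternal-health factsheet data: the South leads on all
#' pillars, the Northeast lags on utilisation while ranking high on
#' empowerment, the Central zone lags on empowerment.
#'
#' @param zones zone codes (subset of [ZONES]).
#' @param pillars pillar ids.
#' @return numeric matrix zones x pillars.
#' @export
default_zone_means <- function(zones = ZONES, pillars = PILLARS) {
  base <- matrix(c(
    # MHU, WE, DC
    62, 48, 56,   # C
    58, 54, 60,   # E
    74, 64, 63,   # N
    50, 62, 62,   # NE
    84, 70, 80,   # S
    80, 56, 66),  # W
    nrow = 6, byrow = TRUE,
    dimnames = list(ZONES, PILLARS))
  m <- base[zones, seq_along(pillars), drop = FALSE]
  colnames(m) <- pillars
  m
}

#' Generate a synthetic survey table and registry
#'
#' Draws an indicator table and matching region registry from a
#' [synthetic_config()]. Region ids follow the `u_`/`r_` naming
#' convention (urban/rural strata alternating within each zone, states
#' synthesised as `<zone><k>`). Identical config and seed give
#' bit-identical output; the RNG state of the caller is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (an [indicator_table()], `survey_round`
#'   `"synthetic"`), `registry` (region registry data.frame), and
#'   `n_clipped` (count of values clipped into [0, 100]).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  zones <- names(config$zone_sizes)
  registry <- do.call(rbind, lapply(zones, function(z) {
    n <- config$zone_sizes[[z]]
    state <- paste0(z, rep(seq_len(ceiling(n / 2)), each = 2, length.out = n))
    res <- rep(c("urban", "rural"), length.out = n)
    data.frame(region_id = paste0(substr(res, 1, 1), "_", state),
               state = state, zone = z, residence = res,
               stringsAsFactors = FALSE)
  }))
  registry <- validate_registry(registry)

  pillars <- names(config$pillar_spec)
  ind_ids <- unlist(lapply(pillars, function(p) {
    sprintf("%s_%02d", tolower(p), seq_len(config$pillar_spec[[p]]))
  }))
  ind_pillar <- rep(pillars, config$pillar_spec)
  offsets <- stats::rnorm(length(ind_ids), 0, config$indicator_sd)

  n_r <- nrow(registry)
  mu <- config$zone_means[as.character(registry$zone), ind_pillar, drop = FALSE]
  noise <- matrix(stats::rnorm(n_r * length(ind_ids), 0, config$region_sd),
                  n_r, length(ind_ids))
  raw <- mu + matrix(offsets, n_r, length(ind_ids), byrow = TRUE) + noise
  n_clipped <- sum(raw < 0 | raw > 100)
  values <- pmin(pmax(raw, 0), 100)
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_r * length(ind_ids)) < config$missing_rate,
                   n_r, length(ind_ids))
    values[mask] <- NA_real_
  }
  dimnames(values) <- list(registry$region_id, ind_ids)
  list(table = indicator_table(values, survey_round = "synthetic"),
       registry = registry, n_clipped = n_clipped)
}

#' Pillar configuration matching a synthetic survey
#'
#' Each synthetic indicator becomes its own equally weighted dimension
#' within its pillar.
#'
#' @param config a [synthetic_config()].
#' @return a [pillar_config()].
#' @export
synthetic_pillar_config <- function(config) {
  pillars <- lapply(names(config$pillar_spec), function(p) {
    ids <- sprintf("%s_%02d", tolower(p), seq_len(config$pillar_spec[[p]]))
    lapply(ids, function(i) list(id = i, indicators = i, weight = 1))
  })
  names(pillars) <- names(config$pillar_spec)
  pillar_config(pillars)
}

#' Monte-Carlo recovery experiment over the full pipeline
#'
#' Repeatedly generates a synthetic survey, runs
#' score -> classify -> favourability -> MANOVA -> post-hoc, and
#' summarises how well the injected structure is recovered:
#' \itemize{
#'   \item `fav_rank_mae`: mean absolute error between the zone ranking
#'     implied by the favourability scores and the ranking of the
#'     injected zone means, averaged over pillars and replicates;
#'   \item `rejection_rate`: per-pillar share of replicates in which the
#'     one-way F test rejects at `alpha` (type-I rate when zone means
#'     are equal, power otherwise);
#'   \item `posthoc_tpr` / `posthoc_fpr`: share of truly shifted zone
#'     pairs flagged significant, and of null pairs flagged significant,
#'     across pillars and replicates.
#' }
#' Replicate r uses seed `config$seed + r` so the experiment is
#' reproducible yet replicates are independent draws.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param alpha significance level (default 0.05).
#' @return list with elements `rejection_rate` (named per pillar),
#'   `fav_rank_mae`, `posthoc_tpr`, `posthoc_fpr` (NA when no pair of
#'   the relevant class exists) and `n_replicates`.
#' @export
recovery_experiment <- function(config, n_replicates, alpha = 0.05) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  pillars <- names(config$pillar_spec)
  pcfg <- synthetic_pillar_config(config)
  zones <- names(config$zone_sizes)
  true_diff <- lapply(pillars, function(p) {
    pairs <- utils::combn(zones, 2)
    apply(pairs, 2, function(ab) {
      config$zone_means[ab[1], p] != config$zone_means[ab[2], p]
    })
  })
  names(true_diff) <- pillars

  reject <- matrix(FALSE, n_replicates, length(pillars),
                   dimnames = list(NULL, pillars))
  rank_err <- numeric(0)
  tp <- fp <- pos <- neg <- 0
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    sim <- generate_survey(cfg_r)
    scores <- score_all(sim$table, pcfg, sim$registry)
    asn <- assign_quantiles(scores)
    fav <- favourability(asn, sim$registry, pillars)
    mv <- zonal_manova(scores, sim$registry)
    reject[r, ] <- mv$univariate$p[match(pillars, mv$univariate$pillar_id)] < alpha
    for (p in pillars) {
      fz <- fav$score[fav$pillar_id == p][match(zones, fav$zone[fav$pillar_id == p])]
      rank_err <- c(rank_err,
                    mean(abs(rank(fz, ties.method = "average") -
                               rank(config$zone_means[, p], ties.method = "average"))))
      ph <- bonferroni_posthoc(scores, sim$registry, p, alpha)
      truth <- true_diff[[p]]
      tp <- tp + sum(ph$significant & truth)
      fp <- fp + sum(ph$significant & !truth)
      pos <- pos + sum(truth)
      neg <- neg + sum(!truth)
    }
  }
  list(rejection_rate = colMeans(reject),
       fav_rank_mae = mean(rank_err),
       posthoc_tpr = if (pos) tp / pos else NA_real_,
       posthoc_fpr = if (neg) fp / neg else NA_real_,
       n_replicates = n_replicates)
}
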