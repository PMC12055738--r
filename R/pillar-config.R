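#' Construct a pillar configuration
#'
#' A pillar configuration maps indicators into thematic pillars through an
#' intermediate dimension layer, mirroring the SPI hierarchy
#' indicator -> dimension -> pillar. In the default configuration every
#' indicator forms its own dimension with weight 1, which makes the pillar
#' score an unweighted average over the pillar's non-missing indicators.
#'
#' @param pillars named list; each element describes one pillar as a list
#'   of dimensions, each dimension being
#'   `list(id =, indicators = character(), weight = 1)`.
#' @param polarity named character vector mapping indicator ids to
#'   `"direct"` (higher is better, the default) or `"inverse"` (the value
#'   is replaced by `100 - x` before scoring).
#' @return an object of class `pillar_config`.
#' @export
pillar_config <- function(pillars, polarity = character(0)) {
  if (!length(pillars) || is.null(names(pillars)) || any(names(pillars) == "")) {
    validation_error("pillars must be a non-empty named list")
  }
  seen <- character(0)
  for (p in names(pillars)) {
    dims <- pillars[[p]]
    if (!length(dims)) {
      validation_error(sprintf("pillar '%s' has no dimensions", p))
    }
    for (k in seq_along(dims)) {
      d <- dims[[k]]
      if (is.null(d$indicators) || !length(d$indicators)) {
        validation_error(sprintf("pillar '%s': dimension %d has no indicators", p, k))
      }
      d$id <- d$id %||% paste0("dim", k)
      d$weight <- d$weight %||% 1
      if (!is.numeric(d$weight) || length(d$weight) != 1L || d$weight < 0) {
        validation_error(sprintf(
          "pillar '%s', dimension '%s': weight must be a nonnegative scalar", p, d$id))
      }
      d$indicators <- as.character(d$indicators)
      dims[[k]] <- d
    }
    w <- vapply(dims, `[[`, numeric(1), "weight")
    if (all(w == 0)) {
      validation_error(sprintf("pillar '%s': all dimension weights are zero", p))
    }
    inds <- unlist(lapply(dims, `[[`, "indicators"))
    clash <- intersect(inds, seen)
    if (length(clash) || anyDuplicated(inds)) {
      dupped <- unique(c(clash, inds[duplicated(inds)]))
      validation_error("indicator assigned more than once: ",
                       paste(dupped, collapse = ", "))
    }
    seen <- c(seen, inds)
    pillars[[p]] <- dims
  }
  if (length(polarity)) {
    bad <- setdiff(unique(polarity), c("direct", "inverse"))
    if (length(bad)) {
      validation_error("polarity values must be 'direct' or 'inverse', got: ",
                       paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(polarity), seen)
    if (length(unknown)) {
      validation_error("polarity names an unconfigured indicator: ",
                       paste(unknown, collapse = ", "))
    }
  }
  structure(list(pillars = pillars, polarity = polarity),
            class = "pillar_config")
}

#' Read a pillar configuration from a YAML file
#'
#' Two spellings are accepted per pillar: an explicit `dimensions` list
#' (each with `id`, `indicators` and optional `weight`), or a flat
#' `indicators` list, shorthand for one single-indicator dimension per
#' indicator with weight 1 — the hierarchy's special case in which the
#' pillar score reduces to a plain average of indicators. A top-level
#' `polarity` map (indicator -> direct/inverse) is optional.
#'
#' @param path path to the YAML file.
#' @return a [pillar_config()].
#' @export
read_pillar_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("spizonal_io_error", "error", "condition")))
  }
  spec <- yaml::read_yaml(path)
  if (is.null(spec$pillars)) validation_error("config has no 'pillars' entry")
  pillars <- lapply(spec$pillars, function(p) {
    if (!is.null(p$dimensions)) {
      p$dimensions
    } else if (!is.null(p$indicators)) {
      lapply(p$indicators, function(i) list(id = i, indicators = i, weight = 1))
    } else {
      validation_error("each pillar needs 'dimensions' or 'indicators'")
    }
  })
  polarity <- unlist(spec$polarity %||% list())
  pillar_config(pillars, polarity = polarity)
}

#' Default three-pillar configuration
#'
#' Ships the package's default mapping of 22 NFHS-style indicators into
#' the pillars MHU (8 indicators), WE (7) and DC (7), each indicator its
#' own equally weighted dimension. The split is a documented placeholder:
#' the authoritative indicator-to-pillar assignment is survey-specific
#' and should be supplied as configuration for real analyses.
#'
#' @return a [pillar_config()].
#' @export
default_pillar_config <- function() {
  read_pillar_config(system.file("extdata", "pillar_config.yaml",
                                 package = "spizonal", mustWork = TRUE))
}

#' Indicators referenced by a pillar configuration
#'
#' @param config a [pillar_config()].
#' @param pillar optional pillar id to restrict to.
#' @return character vector of indicator ids.
#' @export
config_indicators <- function(config, pillar = NULL) {
  pl <- config$pillars
  if (!is.null(pillar)) pl <- pl[pillar]
  unname(unlist(lapply(pl, function(dims) lapply(dims, `[[`, "indicators"))))
}

#' @export
print.pillar_config <- function(x, ...) {
  cat("Pillar configuration\n")
  for (p in names(x$pillars)) {
    dims <- x$pillars[[p]]
    n_ind <- length(config_indicators(x, p))
    cat(sprintf("  %s: %d dimension(s), %d indicator(s)\n", p, length(dims), n_ind))
  }
  n_inv <- sum(x$polarity == "inverse")
  if (n_inv) cat(sprintf("  %d indicator(s) with inverse polarity\n", n_inv))
  invisible(x)
}

# apply polarity: inverse indicators become 100 - x
apply_polarity <- function(table, config) {
  inv <- names(config$polarity)[config$polarity == "inverse"]
  inv <- intersect(inv, colnames(table))
  if (length(inv)) table[, inv] <- 100 - table[, inv, drop = FALSE]
  table
}
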