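#' Read a region registry
#'
#' The registry lists the survey regions (urban or rural strata of states
#' and union territories, e.g. `u_Assam` for urban Assam) together with
#' their state, zone and residence type. It is the reference against which
#' every indicator table is resolved before scoring.
#'
#' @param path path to a CSV with header columns
#'   `region_id,state,zone,residence`.
#' @return a `data.frame` with columns `region_id` (character, unique),
#'   `state` (character), `zone` (factor with levels [ZONES]) and
#'   `residence` (factor with levels `urban`, `rural`).
#' @seealso [read_indicator_table()], [generate_survey()]
#' @export
read_region_registry <- function(path) {
  df <- read_csv_strict(path)
  validate_registry(df)
}

#' Validate a region registry data frame
#'
#' @param df data.frame with columns `region_id`, `state`, `zone`,
#'   `residence`.
#' @return the validated registry with `zone` and `residence` as factors.
#' @export
validate_registry <- function(df) {
  required <- c("region_id", "state", "zone", "residence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    validation_error("registry is missing column(s): ",
                     paste(missing_cols, collapse = ", "))
  }
  df$region_id <- as.character(df$region_id)
  dup <- unique(df$region_id[duplicated(df$region_id)])
  if (length(dup)) {
    validation_error("duplicate region_id in registry: ",
                     paste(dup, collapse = ", "))
  }
  bad_zone <- which(!df$zone %in% ZONES)
  if (length(bad_zone)) {
    validation_error(sprintf(
      "unknown zone token '%s' in registry row %d (region %s); valid zones: %s",
      df$zone[bad_zone[1]], bad_zone[1], df$region_id[bad_zone[1]],
      paste(ZONES, collapse = ", ")))
  }
  bad_res <- which(!df$residence %in% c("urban", "rural"))
  if (length(bad_res)) {
    validation_error(sprintf(
      "residence must be 'urban' or 'rural'; got '%s' in row %d",
      df$residence[bad_res[1]], bad_res[1]))
  }
  df$zone <- factor(df$zone, levels = ZONES)
  df$residence <- factor(df$residence, levels = c("urban", "rural"))
  rownames(df) <- NULL
  df[required]
}

#' Write a region registry to CSV
#'
#' @param registry registry data.frame as returned by
#'   [read_region_registry()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_region_registry <- function(registry, path) {
  out <- registry
  out$zone <- as.character(out$zone)
  out$residence <- as.character(out$residence)
  write_csv_strict(out, path)
}

# every table region must resolve against the registry; unresolvable ids
# are a hard error, never silently dropped
check_regions_resolve <- function(region_ids, registry) {
  unknown <- setdiff(region_ids, registry$region_id)
  if (length(unknown)) {
    validation_error("region_id not present in registry: ",
                     paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
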