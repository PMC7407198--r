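#' Write a long-format panel table
#'
#' One measurement record per row; the tidy CSV is the interchange format of
#' the whole pipeline (wide matrices are derived objects, never stored).
#'
#' @param records Tibble of measurement records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(records, path) {
  cols <- c("patient_id", "group", "location", "depth", "analyte", "value", "qc")
  readr::write_csv(records[, intersect(cols, names(records))], path)
  invisible(path)
}

#' Read and validate a long-format panel table
#'
#' Validates every row against the analyte catalog and the study design:
#' known analyte, group, depth and location labels, no posterior-capsule
#' readings at the radial layer (that location cannot be collected there),
#' nonnegative values, and known QC flags. Errors list the offending rows
#' and fields.
#'
#' @param path CSV with columns `patient_id, group, location, depth,
#'   analyte, value, qc`.
#' @param catalog Analyte catalog, by default [panel_catalog()].
#' @return A tibble of validated measurement records.
#' @export
read_panel_table <- function(path, catalog = panel_catalog()) {
  if (!file.exists(path)) {
    stop(sprintf("panel table '%s' does not exist", path), call. = FALSE)
  }
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "group", "location", "depth", "analyte", "value", "qc")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols) > 0) {
    stop(sprintf("panel table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_records(rec, catalog)
}

#' Validate measurement records against catalog and design
#'
#' @param records Tibble of measurement records.
#' @param catalog Analyte catalog.
#' @return The records, invisibly usable, after validation.
#' @export
validate_records <- function(records, catalog = panel_catalog()) {
  problems <- character(0)
  row_of <- function(idx) paste0("row ", idx)
  bad <- which(!records$analyte %in% catalog$analyte)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: unknown analyte '%s'", row_of(bad), records$analyte[bad]))
  }
  bad <- which(!records$group %in% GROUPS)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: unknown group '%s'", row_of(bad), records$group[bad]))
  }
  bad <- which(!records$depth %in% DEPTHS)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: unknown depth '%s'", row_of(bad), records$depth[bad]))
  }
  ok_loc <- mapply(function(l, d) d %in% DEPTHS && l %in% DEPTH_LOCATIONS[[d]],
                   records$location, records$depth)
  bad <- which(records$depth %in% DEPTHS & !ok_loc)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: location '%s' is not collected at depth '%s'",
      row_of(bad), records$location[bad], records$depth[bad]))
  }
  bad <- which(is.na(records$value) | records$value < 0)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: field 'value' must be a nonnegative number", row_of(bad)))
  }
  bad <- which(!records$qc %in% c("ok", "below_lloq", "above_uloq"))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "%s: unknown qc flag '%s'", row_of(bad), records$qc[bad]))
  }
  if (length(problems) > 0) {
    stop(paste0("invalid panel table:\n  ",
                paste(utils::head(problems, 20), collapse = "\n  "),
                if (length(problems) > 20) sprintf("\n  ... and %d more", length(problems) - 20) else ""),
         call. = FALSE)
  }
  records
}

#' Read one network's normalized-radiality reference column
#'
#' The package ships two reference fixtures of published normalized-radiality
#' values for the six knee-tissue networks, typed to the two decimals at
#' which they were reported (one CSV per depth; one value column per patient
#' group). This reads one network's column as an ordered node-to-value
#' mapping.
#'
#' @param path Fixture CSV with a `node` column and one column per group.
#' @param group Which network column to read (`"primary"`, `"aseptic"`,
#'   `"septic"`).
#' @return Named numeric vector of 30 normalized radiality values in catalog
#'   node order.
#' @export
#' @examples
#' atl <- radnet_fixture_path("ATL")
#' v <- read_radiality_fixture(atl, "primary")
#' sum(v == 1.13)  # 16
read_radiality_fixture <- function(path, group) {
  if (!file.exists(path)) {
    stop(sprintf("fixture '%s' does not exist", path), call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"node" %in% names(tab) || !group %in% names(tab)) {
    stop(sprintf("fixture must have a 'node' column and a '%s' column", group),
         call. = FALSE)
  }
  cat30 <- panel_catalog()
  unknown <- setdiff(tab$node, cat30$analyte)
  if (length(unknown) > 0) {
    stop(sprintf("fixture contains unknown nodes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) != nrow(cat30) || anyDuplicated(tab$node) > 0) {
    stop(sprintf("fixture must list each of the %d catalog nodes exactly once (found %d rows)",
                 nrow(cat30), nrow(tab)), call. = FALSE)
  }
  v <- tab[[group]][match(cat30$analyte, tab$node)]
  stats::setNames(v, cat30$analyte)
}

#' Path to a packaged radiality reference fixture
#'
#' @param depth `"ATL"` or `"RTL"`.
#' @return Path to the installed fixture CSV.
#' @export
radnet_fixture_path <- function(depth = c("ATL", "RTL")) {
  depth <- match.arg(depth)
  fn <- sprintf("radiality_reference_%s.csv", tolower(depth))
  path <- system.file("extdata", fn, package = "radnet")
  if (!nzchar(path)) stop("packaged fixture not found", call. = FALSE)
  path
}

#' Write a radiality table as CSV
#'
#' @param table A `radiality_table` (see [radiality_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_radiality_table <- function(table, path) {
  out <- tibble::tibble(
    group = table$network_id[["group"]],
    depth = table$network_id[["depth"]],
    analyte = table$rows$analyte,
    raw_radiality = table$rows$raw_radiality,
    normalized_radiality = table$rows$normalized_radiality,
    call = table$rows$call
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a cohort configuration as a plain-text file
#'
#' YAML key/value schema: scalar fields at top level, `censor_bounds` as a
#' per-analyte map of `[lloq, uloq]`, `analyte_effects` as a list of
#' `{analyte, group, depth, meanlog, sdlog}` records.
#'
#' @param config A [cohort_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  obj <- list(
    n_patients_per_group = as.list(config$n_patients_per_group),
    outlier_rate = config$outlier_rate,
    outlier_multiplier = config$outlier_multiplier,
    seed = config$seed,
    censor_bounds = lapply(split(config$censor_bounds, seq_len(nrow(config$censor_bounds))),
                           function(r) list(analyte = r$analyte, lloq = r$lloq, uloq = r$uloq)),
    analyte_effects = lapply(split(config$analyte_effects, seq_len(nrow(config$analyte_effects))),
                             function(r) list(analyte = r$analyte, group = r$group,
                                              depth = r$depth, meanlog = r$meanlog,
                                              sdlog = r$sdlog))
  )
  names(obj$censor_bounds) <- NULL
  names(obj$analyte_effects) <- NULL
  writeLines(yaml::as.yaml(obj, precision = 17), path)
  invisible(path)
}

#' Read a cohort configuration from a plain-text file
#'
#' @param path File written by [write_cohort_config()] (or hand-authored to
#'   the same schema).
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  obj <- yaml::read_yaml(path)
  eff <- dplyr::bind_rows(lapply(obj$analyte_effects, tibble::as_tibble))
  cb <- dplyr::bind_rows(lapply(obj$censor_bounds, tibble::as_tibble))
  cohort_config(
    n_patients_per_group = unlist(obj$n_patients_per_group),
    analyte_effects = eff,
    censor_bounds = cb,
    outlier_rate = obj$outlier_rate,
    outlier_multiplier = obj$outlier_multiplier,
    seed = obj$seed
  )
}
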