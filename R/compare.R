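#' Cross-network comparison of significant nodes
#'
#' Synthesizes the six radiality tables into: per-network low/high sets;
#' per-group depth-union low sets (a node belongs to a group if it is a
#' significant low node at either depth — the per-depth breakdown is
#' retained); driver sets per group x depth — the nodes whose low status
#' differs from the reference group's network at the same depth, annotated
#' as `gained` (low here, not in reference) or `lost` (low in reference,
#' not here); and the overlap map assigning each analyte to the groups in
#' whose depth-union low set it appears. Low-radiality sets drive the
#' comparison (peripheral nodes are the likely contributors to network
#' dysregulation); high sets are reported alongside.
#'
#' @param tables Named list of `radiality_table`, one per group x depth
#'   (names `group.depth`), e.g. from [analyze_cohort()].
#' @param reference_group Reference for driver sets (default `"primary"`).
#' @return Object of class `network_comparison`.
#' @export
build_comparison <- function(tables, reference_group = "primary") {
  ids <- tidyr::expand_grid(group = GROUPS, depth = DEPTHS)
  wanted <- paste(ids$group, ids$depth, sep = ".")
  missing_nets <- setdiff(wanted, names(tables))
  if (length(missing_nets) > 0) {
    stop(sprintf("missing network table(s): %s",
                 paste(missing_nets, collapse = ", ")), call. = FALSE)
  }
  if (!reference_group %in% GROUPS) {
    stop(sprintf("unknown reference group '%s'", reference_group),
         call. = FALSE)
  }
  cat30 <- panel_catalog()
  in_catalog_order <- function(x) cat30$analyte[cat30$analyte %in% x]
  call_set <- function(key, what) {
    rows <- tables[[key]]$rows
    in_catalog_order(rows$analyte[rows$call == what])
  }
  low <- lapply(wanted, call_set, what = "low")
  high <- lapply(wanted, call_set, what = "high")
  names(low) <- names(high) <- wanted

  union_low <- lapply(GROUPS, function(g) {
    in_catalog_order(unique(unlist(low[paste(g, DEPTHS, sep = ".")])))
  })
  names(union_low) <- GROUPS

  drivers <- list()
  for (g in GROUPS) {
    for (d in DEPTHS) {
      ref <- low[[paste(reference_group, d, sep = ".")]]
      cur <- low[[paste(g, d, sep = ".")]]
      drivers[[paste(g, d, sep = ".")]] <- list(
        gained = in_catalog_order(setdiff(cur, ref)),
        lost = in_catalog_order(setdiff(ref, cur))
      )
    }
  }

  all_low <- in_catalog_order(unique(unlist(union_low)))
  overlap <- lapply(all_low, function(a) {
    GROUPS[vapply(GROUPS, function(g) a %in% union_low[[g]], logical(1))]
  })
  names(overlap) <- all_low

  structure(
    list(
      reference_group = reference_group,
      low_sets = low,
      high_sets = high,
      union_low_sets = union_low,
      driver_sets = drivers,
      overlap_map = overlap
    ),
    class = "network_comparison"
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> reference group: %s\n", x$reference_group))
  for (g in names(x$union_low_sets)) {
    cat(sprintf("  %s depth-union low set: %s\n", g,
                paste_or_none(x$union_low_sets[[g]])))
  }
  shared <- names(x$overlap_map)[vapply(x$overlap_map, length, integer(1)) > 1]
  cat(sprintf("  nodes low in more than one group: %s\n", paste_or_none(shared)))
  invisible(x)
}

paste_or_none <- function(x) {
  if (length(x) == 0) "none" else paste(x, collapse = ", ")
}

#' Render the comparison report
#'
#' One human-readable text report (per-network tables with significance
#' markers and thresholds, driver sets, overlap map) and one
#' machine-readable JSON twin carrying the same content. Empty sets are
#' stated as "none" rather than omitted.
#'
#' @param comparison A `network_comparison`.
#' @param tables The radiality tables used to build it.
#' @param stats Optional list of `anova_result` to summarize alongside.
#' @param path_txt,path_json Output paths (`NULL` to skip writing).
#' @return List with `text` (character vector of report lines) and `json`
#'   (the report object), invisibly.
#' @export
render_report <- function(comparison, tables, stats = NULL,
                          path_txt = NULL, path_json = NULL) {
  lines <- c("Radiality network comparison report",
             sprintf("reference group: %s", comparison$reference_group), "")
  for (key in names(tables)) {
    tab <- tables[[key]]
    s <- tab$network_stats
    lines <- c(lines,
      sprintf("network %s x %s (diameter %.3f, mean 1, sd %.3f, cuts [%.3f, %.3f])",
              tab$network_id[["group"]], tab$network_id[["depth"]],
              s$diameter, s$sd_normalized, s$low_cut, s$high_cut))
    marked <- ifelse(tab$rows$call == "ns", "",
                     ifelse(tab$rows$call == "low", " *low*", " *high*"))
    lines <- c(lines, sprintf("  %-12s %6.2f%s", tab$rows$analyte,
                              tab$rows$normalized_radiality, marked), "")
  }
  lines <- c(lines, "depth-union low sets:")
  for (g in names(comparison$union_low_sets)) {
    lines <- c(lines, sprintf("  %s: %s", g,
                              paste_or_none(comparison$union_low_sets[[g]])))
  }
  lines <- c(lines, "", "driver sets vs reference (gained/lost low status):")
  for (key in names(comparison$driver_sets)) {
    dr <- comparison$driver_sets[[key]]
    lines <- c(lines,
      sprintf("  %s: gained %s; lost %s", key,
              paste_or_none(dr$gained), paste_or_none(dr$lost)))
  }
  lines <- c(lines, "", "overlap map (node -> groups with low status at either depth):")
  if (length(comparison$overlap_map) == 0) {
    lines <- c(lines, "  none")
  } else {
    for (a in names(comparison$overlap_map)) {
      lines <- c(lines, sprintf("  %s: %s", a,
                                paste(comparison$overlap_map[[a]], collapse = ", ")))
    }
  }
  if (!is.null(stats)) {
    flagged <- names(stats)[vapply(stats, function(s) any(s$posthoc$flagged),
                                   logical(1))]
    lines <- c(lines, "", sprintf("ANOVA: analytes with flagged contrasts: %s",
                                  paste_or_none(flagged)))
  }

  json <- list(
    reference_group = comparison$reference_group,
    networks = lapply(tables, function(tab) {
      list(group = unname(tab$network_id[["group"]]),
           depth = unname(tab$network_id[["depth"]]),
           stats = tab$network_stats,
           nodes = tab$rows)
    }),
    low_sets = comparison$low_sets,
    high_sets = comparison$high_sets,
    union_low_sets = comparison$union_low_sets,
    driver_sets = comparison$driver_sets,
    overlap_map = comparison$overlap_map
  )
  if (!is.null(path_txt)) writeLines(lines, path_txt)
  if (!is.null(path_json)) {
    jsonlite::write_json(json, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(text = lines, json = json))
}
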