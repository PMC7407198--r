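#' Drop readings censored by the quantitation limits
#'
#' Readings flagged below the LLOQ or above the ULOQ are omitted before any
#' statistics are computed. Removal counts per analyte are attached as
#' attribute `"censor_log"`.
#'
#' @param records Validated measurement records.
#' @return The records with `qc == "ok"` only.
#' @export
drop_censored <- function(records) {
  dropped <- records[records$qc != "ok", , drop = FALSE]
  kept <- records[records$qc == "ok", , drop = FALSE]
  log <- if (nrow(dropped) > 0) {
    dplyr::count(dropped[, c("analyte", "qc")], analyte, qc, name = "n_removed")
  } else {
    tibble::tibble(analyte = character(0), qc = character(0),
                   n_removed = integer(0))
  }
  attr(kept, "censor_log") <- log
  kept
}

#' Tukey 1.5 x IQR outlier filter
#'
#' Quartiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7); values strictly outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are removed. With fewer than four values
#' no filtering is attempted (a warning is raised and the input returned
#' unchanged): quartile fences from two or three points are not meaningful.
#'
#' @param values Numeric vector of readings.
#' @return List with `kept` and `removed` numeric vectors.
#' @export
#' @examples
#' iqr_outlier_filter(c(1, 2, 3, 4, 100))  # removes 100
iqr_outlier_filter <- function(values) {
  if (length(values) == 0) stop("cannot filter an empty vector", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (length(values) < 4) {
    warning("fewer than 4 values; outlier filtering skipped")
    return(list(kept = values, removed = numeric(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- values < lo | values > hi
  list(kept = values[!out], removed = values[out])
}

#' Apply the IQR outlier filter across the cohort
#'
#' The filter runs per analyte x group x depth x location across patients —
#' before location averaging, the only point where single errant assay
#' readings still exist as such. Removal counts are attached as attribute
#' `"outlier_log"`.
#'
#' @param records Censor-filtered measurement records.
#' @return Records with outliers removed.
#' @export
filter_outliers <- function(records) {
  key <- paste(records$analyte, records$group, records$depth, records$location,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    if (length(idx) < 4) return(idx)
    v <- records$value[idx]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    idx[v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr]
  }), use.names = FALSE)
  keep <- sort(keep)
  removed <- records[-keep, , drop = FALSE]
  kept <- records[keep, , drop = FALSE]
  log <- if (nrow(removed) > 0) {
    dplyr::count(removed[, c("analyte", "group", "depth", "location")],
                 analyte, group, depth, location, name = "n_removed")
  } else {
    tibble::tibble(analyte = character(0), group = character(0),
                   depth = character(0), location = character(0),
                   n_removed = integer(0))
  }
  attr(kept, "outlier_log") <- log
  kept
}

#' Average anatomical locations within each depth
#'
#' The four ATL locations (three for RTL) are averaged per patient and
#' analyte to one reading per depth. If every location for a patient x depth
#' x analyte was removed upstream, that entry is simply absent (missing).
#'
#' @param records Censor- and outlier-filtered records.
#' @return Tibble with columns `patient_id`, `group`, `depth`, `analyte`,
#'   `value` (the location mean) and `n_locations` (how many locations
#'   survived filtering).
#' @export
depth_average <- function(records) {
  grp <- records |>
    dplyr::group_by(patient_id, group, depth, analyte) |>
    dplyr::summarise(n_locations = dplyr::n(), value = mean(value),
                     .groups = "drop")
  grp[, c("patient_id", "group", "depth", "analyte", "value", "n_locations")]
}

#' Normalize each analyte to its global maximum
#'
#' Every depth-averaged value is divided by the maximum for that analyte
#' taken jointly across all groups, depths and patients, so the six networks
#' share one normalized scale per analyte and the maximum maps to exactly 1.
#' Tied maxima all map to 1.
#'
#' @param depth_averaged Output of [depth_average()].
#' @param catalog Analyte catalog the data must cover; an analyte with no
#'   values at all is an error naming it. Pass `NULL` to normalize whatever
#'   analytes are present (for subset work).
#' @return The same tibble with `value` rescaled to \[0, 1\].
#' @export
max_normalize <- function(depth_averaged, catalog = panel_catalog()) {
  if (!is.null(catalog)) {
    absent <- setdiff(catalog$analyte, unique(depth_averaged$analyte))
    if (length(absent) > 0) {
      stop(sprintf("no data to normalize for analyte(s): %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  depth_averaged |>
    dplyr::group_by(analyte) |>
    dplyr::mutate(value = value / max(value)) |>
    dplyr::ungroup()
}

#' Assemble the response matrix of one network
#'
#' Builds the nodes x replicates matrix of normalized responses for one
#' group x depth network, with nodes fixed to catalog order. Replicates are
#' the group's patients (locations were already averaged within depth).
#' Missing entries are resolved per `missing_policy`:
#' \describe{
#'   \item{`impute_mean`}{(default) a gap is filled with the node's mean
#'     over the other patients, keeping replicate indices aligned across
#'     nodes as the distance sum requires;}
#'   \item{`pairwise_complete`}{gaps are kept as `NA` and each pairwise
#'     distance later sums over the replicates both nodes share.}
#' }
#'
#' @param normalized Output of [max_normalize()].
#' @param group,depth Network identifier.
#' @param missing_policy `"impute_mean"` or `"pairwise_complete"`.
#' @param catalog Analyte catalog.
#' @return An object of class `response_matrix`: list with `network_id`,
#'   `nodes`, `replicates`, `values` (nodes x replicates matrix),
#'   `n_replicates`, `n_imputed`.
#' @export
assemble_response_matrix <- function(normalized, group, depth,
                                     missing_policy = c("impute_mean", "pairwise_complete"),
                                     catalog = panel_catalog()) {
  missing_policy <- match.arg(missing_policy)
  sub <- normalized[normalized$group == group & normalized$depth == depth, ]
  if (nrow(sub) == 0) {
    stop(sprintf("no data for network %s x %s", group, depth), call. = FALSE)
  }
  replicates <- sort(unique(sub$patient_id))
  m <- matrix(NA_real_, nrow = nrow(catalog), ncol = length(replicates),
              dimnames = list(catalog$analyte, replicates))
  m[cbind(match(sub$analyte, catalog$analyte),
          match(sub$patient_id, replicates))] <- sub$value

  empty <- rownames(m)[rowSums(!is.na(m)) == 0]
  if (length(empty) > 0) {
    stop(sprintf("network %s x %s has node(s) with no data: %s",
                 group, depth, paste(empty, collapse = ", ")), call. = FALSE)
  }
  n_imputed <- 0L
  if (missing_policy == "impute_mean" && anyNA(m)) {
    n_imputed <- sum(is.na(m))
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- means[idx[, 1]]
  }
  structure(
    list(
      network_id = c(group = group, depth = depth),
      nodes = rownames(m),
      replicates = replicates,
      values = m,
      n_replicates = length(replicates),
      n_imputed = n_imputed,
      missing_policy = missing_policy
    ),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %s x %s: %d nodes x %d replicates (%s%s)\n",
              x$network_id[["group"]], x$network_id[["depth"]],
              length(x$nodes), x$n_replicates, x$missing_policy,
              if (x$n_imputed > 0) sprintf(", %d imputed", x$n_imputed) else ""))
  invisible(x)
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Fixed stage order: censoring omission, 1.5xIQR outlier removal per
#' analyte x group x depth x location, location averaging within depth,
#' per-analyte maximum normalization across all networks, then one response
#' matrix per group x depth. Permuting averaging and normalization changes
#' the result; the order matches the analysis this pipeline models.
#'
#' @param records Validated measurement records.
#' @param missing_policy Passed to [assemble_response_matrix()].
#' @param catalog Analyte catalog.
#' @return List with `matrices` (named `group.depth` list of
#'   `response_matrix`), `normalized` (the long normalized table), and `qc`
#'   (censoring/outlier/imputation counts).
#' @export
preprocess_cohort <- function(records,
                              missing_policy = c("impute_mean", "pairwise_complete"),
                              catalog = panel_catalog()) {
  missing_policy <- match.arg(missing_policy)
  kept <- drop_censored(records)
  censor_log <- attr(kept, "censor_log")
  filt <- filter_outliers(kept)
  outlier_log <- attr(filt, "outlier_log")
  avg <- depth_average(filt)
  norm <- max_normalize(avg)

  ids <- tidyr::expand_grid(group = GROUPS, depth = DEPTHS)
  mats <- lapply(seq_len(nrow(ids)), function(i) {
    assemble_response_matrix(norm, ids$group[i], ids$depth[i],
                             missing_policy = missing_policy,
                             catalog = catalog)
  })
  names(mats) <- paste(ids$group, ids$depth, sep = ".")
  list(
    matrices = mats,
    normalized = norm,
    qc = list(
      n_input = nrow(records),
      n_censored = nrow(records) - nrow(kept),
      censor_log = censor_log,
      n_outliers_removed = nrow(kept) - nrow(filt),
      outlier_log = outlier_log,
      n_imputed = sum(vapply(mats, function(m) m$n_imputed, integer(1)))
    )
  )
}

#' Write a preprocessing QC report
#'
#' Emits the censoring, outlier-removal and imputation counts as both a
#' human-readable text file and a machine-readable JSON twin.
#'
#' @param qc The `qc` element of [preprocess_cohort()]'s result.
#' @param path_txt,path_json Output paths (either may be `NULL` to skip).
#' @return The QC list, invisibly.
#' @export
write_qc_report <- function(qc, path_txt = NULL, path_json = NULL) {
  if (!is.null(path_txt)) {
    lines <- c(
      "Preprocessing QC report",
      sprintf("  input records:        %d", qc$n_input),
      sprintf("  censored (LLOQ/ULOQ): %d", qc$n_censored),
      sprintf("  IQR outliers removed: %d", qc$n_outliers_removed),
      sprintf("  entries imputed:      %d", qc$n_imputed)
    )
    if (nrow(qc$censor_log) > 0) {
      lines <- c(lines, "  censored by analyte:",
                 sprintf("    %-12s %-12s %d", qc$censor_log$analyte,
                         qc$censor_log$qc, qc$censor_log$n_removed))
    }
    writeLines(lines, path_txt)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(n_input = qc$n_input, n_censored = qc$n_censored,
           n_outliers_removed = qc$n_outliers_removed,
           n_imputed = qc$n_imputed,
           censor_log = qc$censor_log, outlier_log = qc$outlier_log),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(qc)
}
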