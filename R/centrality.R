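#' Euclidean distance between two replicate profiles
#'
#' The edge weight of the response network: the square root of the sum over
#' aligned replicates of squared differences of normalized responses. Under
#' the pairwise-complete missing policy, the sum runs over the replicates
#' present in both profiles.
#'
#' @param u,w Equal-length numeric replicate vectors (possibly with `NA`
#'   under the pairwise-complete policy).
#' @return Nonnegative distance.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(u, w) {
  if (length(u) != length(w)) {
    stop("replicate vectors must have equal length", call. = FALSE)
  }
  both <- !is.na(u) & !is.na(w)
  if (!any(both)) {
    stop("no shared replicates between the two profiles", call. = FALSE)
  }
  sqrt(sum((u[both] - w[both])^2))
}

#' Build the complete Euclidean distance network
#'
#' Computes all pairwise node distances of a response matrix, giving the
#' complete weighted graph whose node-to-node distances feed the radiality
#' computation, and its diameter (the maximal pairwise distance).
#'
#' @param m A `response_matrix` (or a plain numeric matrix of nodes x
#'   replicates).
#' @return An object of class `distance_network`: list with `network_id`,
#'   `nodes`, `distances` (symmetric matrix, zero diagonal), `diameter`,
#'   `n_nodes`.
#' @export
build_distance_network <- function(m) {
  if (inherits(m, "response_matrix")) {
    values <- m$values
    network_id <- m$network_id
  } else {
    values <- as.matrix(m)
    network_id <- c(group = NA_character_, depth = NA_character_)
  }
  if (nrow(values) < 2) {
    stop("a network needs at least 2 nodes", call. = FALSE)
  }
  if (anyNA(values)) {
    n <- nrow(values)
    d <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- euclidean_distance(values[i, ], values[j, ])
      }
    }
  } else {
    d <- as.matrix(stats::dist(values, method = "euclidean"))
  }
  structure(
    list(
      network_id = network_id,
      nodes = rownames(values),
      distances = d,
      diameter = max(d),
      n_nodes = nrow(values)
    ),
    class = "distance_network"
  )
}

#' @export
print.distance_network <- function(x, ...) {
  cat(sprintf("<distance_network> %d nodes, diameter %.4g\n",
              x$n_nodes, x$diameter))
  invisible(x)
}

#' All-pairs shortest paths by exhaustive relaxation
#'
#' Floyd-Warshall over the complete weighted graph. On a Euclidean distance
#' network the triangle inequality makes every direct edge already a
#' shortest path, so this matrix equals the direct distance matrix; the
#' operation exists to certify that reduction (and it does detect
#' violations on non-metric inputs).
#'
#' @param net A `distance_network`, or a square distance matrix.
#' @return The all-pairs shortest-path matrix.
#' @export
shortest_path_oracle <- function(net) {
  d <- if (inherits(net, "distance_network")) net$distances else as.matrix(net)
  n <- nrow(d)
  for (k in seq_len(n)) {
    relax <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, relax)
  }
  d
}

#' Radiality centrality of every node
#'
#' For node u, radiality is the average over the other n-1 nodes w of
#' `diameter + 1 - dist(u, w)`: nodes close to everything (small summed
#' distance) score high, peripheral nodes score low. Distances are the
#' direct Euclidean edge weights, which on these networks equal the
#' shortest paths (see [shortest_path_oracle()]).
#'
#' @param net A `distance_network`.
#' @return Named numeric vector of raw radiality values.
#' @export
radiality <- function(net) {
  if (!inherits(net, "distance_network")) {
    stop("radiality expects a distance_network", call. = FALSE)
  }
  n <- net$n_nodes
  if (n < 2) stop("radiality needs at least 2 nodes", call. = FALSE)
  # diagonal is zero, so rowSums covers the sum over w != u
  crad <- (net$diameter + 1) - rowSums(net$distances) / (n - 1)
  stats::setNames(crad, net$nodes)
}

#' Normalize radiality to the network average
#'
#' Divides each raw radiality by the mean over all nodes, putting every
#' network on a common scale with mean exactly 1.
#'
#' @param raw Named numeric vector of raw radiality values.
#' @return Normalized radiality, mean 1.
#' @export
normalize_radiality <- function(raw) {
  if (length(raw) < 1) stop("no radiality values to normalize", call. = FALSE)
  m <- mean(raw)
  if (m == 0) stop("cannot normalize: mean radiality is zero", call. = FALSE)
  raw / m
}

#' Significance rule for normalized radiality
#'
#' Cut points at the mean +/- one standard deviation of the normalized
#' radiality values. The SD convention defaults to the sample (n-1)
#' denominator; the population (n) denominator is available as a switch.
#'
#' @param normalized Numeric vector of normalized radiality values.
#' @param sd_convention `"sample"` or `"population"`.
#' @return Object of class `significance_rule`: list with `center`,
#'   `spread`, `sd_convention`, `low_cut`, `high_cut`.
#' @export
significance_rule <- function(normalized,
                              sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  center <- mean(normalized)
  spread <- stats::sd(normalized)
  if (sd_convention == "population") {
    n <- length(normalized)
    spread <- spread * sqrt((n - 1) / n)
  }
  if (is.na(spread)) spread <- 0
  structure(
    list(center = center, spread = spread, sd_convention = sd_convention,
         low_cut = center - spread, high_cut = center + spread),
    class = "significance_rule"
  )
}

#' Classify nodes against a significance rule
#'
#' Strict thresholds: a node is `low` if its normalized radiality is
#' strictly below `center - spread`, `high` if strictly above
#' `center + spread`, otherwise `ns`. Values exactly on a cut point are
#' `ns`; with zero spread every call is `ns`.
#'
#' @param normalized Named numeric vector of normalized radiality values.
#' @param rule A [significance_rule()] (computed from `normalized` itself
#'   when omitted).
#' @param sd_convention Used only when `rule` is omitted.
#' @return Named character vector of calls (`"low"`, `"high"`, `"ns"`).
#' @export
classify_nodes <- function(normalized, rule = NULL,
                           sd_convention = c("sample", "population")) {
  if (is.null(rule)) {
    rule <- significance_rule(normalized, match.arg(sd_convention))
  }
  call <- rep("ns", length(normalized))
  if (rule$spread > 0) {
    call[normalized < rule$low_cut] <- "low"
    call[normalized > rule$high_cut] <- "high"
  }
  stats::setNames(call, names(normalized))
}

#' Radiality table of one network
#'
#' Runs the centrality core on one response matrix: distance network, raw
#' radiality, normalization to the network mean, and mean +/- SD
#' significance calls.
#'
#' @param m A `response_matrix`.
#' @param sd_convention `"sample"` (default) or `"population"`.
#' @return An object of class `radiality_table`: list with `network_id`,
#'   `rows` (tibble: `analyte`, `raw_radiality`, `normalized_radiality`,
#'   `call`) and `network_stats` (mean, sd, cut points, diameter, n_nodes).
#' @export
radiality_table <- function(m, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  net <- build_distance_network(m)
  raw <- radiality(net)
  norm <- normalize_radiality(raw)
  rule <- significance_rule(norm, sd_convention)
  calls <- classify_nodes(norm, rule)
  structure(
    list(
      network_id = net$network_id,
      rows = tibble::tibble(
        analyte = names(raw),
        raw_radiality = unname(raw),
        normalized_radiality = unname(norm),
        call = unname(calls)
      ),
      network_stats = list(
        mean_normalized = rule$center,
        sd_normalized = rule$spread,
        sd_convention = sd_convention,
        low_cut = rule$low_cut,
        high_cut = rule$high_cut,
        diameter = net$diameter,
        n_nodes = net$n_nodes
      )
    ),
    class = "radiality_table"
  )
}

#' @export
print.radiality_table <- function(x, ...) {
  s <- x$network_stats
  cat(sprintf("<radiality_table> %s x %s: %d nodes, diameter %.3f\n",
              x$network_id[["group"]], x$network_id[["depth"]],
              s$n_nodes, s$diameter))
  cat(sprintf("  normalized mean %.3f, sd %.3f (%s), cuts [%.3f, %.3f]\n",
              s$mean_normalized, s$sd_normalized, s$sd_convention,
              s$low_cut, s$high_cut))
  cat(sprintf("  low: %s\n  high: %s\n",
              paste(x$rows$analyte[x$rows$call == "low"], collapse = ", "),
              paste(x$rows$analyte[x$rows$call == "high"], collapse = ", ")))
  invisible(x)
}

#' Network-stats JSON for a radiality table
#'
#' @param table A `radiality_table`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_network_stats <- function(table, path) {
  jsonlite::write_json(
    c(list(group = unname(table$network_id[["group"]]),
           depth = unname(table$network_id[["depth"]])),
      table$network_stats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' End-to-end network analysis of a cohort
#'
#' Preprocesses the records and computes one radiality table per
#' group x depth network.
#'
#' @param records Validated measurement records.
#' @param sd_convention,missing_policy Passed through.
#' @return List with `tables` (named list of `radiality_table`), plus the
#'   `preprocess` result.
#' @export
analyze_cohort <- function(records,
                           sd_convention = c("sample", "population"),
                           missing_policy = c("impute_mean", "pairwise_complete")) {
  sd_convention <- match.arg(sd_convention)
  pre <- preprocess_cohort(records, missing_policy = match.arg(missing_policy))
  tables <- lapply(pre$matrices, radiality_table, sd_convention = sd_convention)
  list(tables = tables, preprocess = pre)
}
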