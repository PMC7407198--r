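# shared fixtures and independent oracles

tiny_config <- function(n = 2, seed = 11L) {
  cohort_config(
    n_patients_per_group = c(primary = n, aseptic = n, septic = n),
    seed = seed
  )
}

# independent brute-force radiality: literal double loop over the defining sum
brute_radiality <- function(d, diameter = max(d)) {
  n <- nrow(d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (w in seq_len(n)) {
      if (w != v) acc <- acc + (diameter + 1 - d[v, w])
    }
    out[v] <- acc / (n - 1)
  }
  out
}

# independent element-by-element Euclidean accumulation
brute_euclid <- function(u, w) {
  acc <- 0
  for (i in seq_along(u)) acc <- acc + (u[i] - w[i])^2
  sqrt(acc)
}

# random response matrix with values in [0, 1]
random_response_matrix <- function(n_nodes = 30, n_rep = 6) {
  m <- matrix(runif(n_nodes * n_rep), n_nodes, n_rep,
              dimnames = list(paste0("node", seq_len(n_nodes)), NULL))
  m
}

# wrap a bare distance matrix as a distance_network
as_network <- function(d) {
  structure(
    list(network_id = c(group = NA_character_, depth = NA_character_),
         nodes = rownames(d) %||% paste0("n", seq_len(nrow(d))),
         distances = d, diameter = max(d), n_nodes = nrow(d)),
    class = "distance_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
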