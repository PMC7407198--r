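test_that("euclidean distance matches hand values and the brute-force oracle", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
  set.seed(101)
  for (i in 1:20) {
    u <- runif(30); w <- runif(30)
    expect_equal(euclidean_distance(u, w), brute_euclid(u, w),
                 tolerance = 1e-12)
  }
})

test_that("the distance network is a complete metric graph with correct diameter", {
  set.seed(103)
  m <- random_response_matrix()
  net <- build_distance_network(m)
  d <- net$distances
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 30))
  expect_equal(sum(upper.tri(d)), 435)  # 30 * 29 / 2 node pairs
  # diameter equals the exhaustive pair-scan maximum
  brute_max <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    brute_max <- max(brute_max, brute_euclid(m[i, ], m[j, ]))
  }
  expect_equal(net$diameter, brute_max, tolerance = 1e-12)
  # triangle inequality over all triples
  viol <- 0
  for (i in 1:30) for (j in 1:30) for (k in 1:30) {
    if (d[i, j] > d[i, k] + d[k, j] + 1e-12) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("duplicated node profiles are mutually at distance zero", {
  m <- random_response_matrix(5, 4)
  m[3, ] <- m[1, ]
  net <- build_distance_network(m)
  expect_equal(net$distances[1, 3], 0)
  expect_equal(net$distances[1, ], net$distances[3, ])
})

test_that("shortest paths reduce to direct edges on Euclidean networks", {
  set.seed(107)
  for (i in 1:5) {
    net <- build_distance_network(random_response_matrix())
    sp <- shortest_path_oracle(net)
    expect_lt(max(abs(sp - net$distances)), 1e-12)
  }
})

test_that("the shortest-path oracle detects a triangle-inequality violation", {
  d <- matrix(c(0, 2, 10,
                2, 0, 3,
                10, 3, 0), 3, 3, byrow = TRUE)
  sp <- shortest_path_oracle(d)
  expect_equal(sp[1, 3], 5)  # two-hop path beats the direct non-metric edge
  expect_equal(sp[1, 2], 2)
})

test_that("the oracle agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(109)
  net <- build_distance_network(random_response_matrix(12, 5))
  g <- igraph::graph_from_adjacency_matrix(net$distances, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ref <- igraph::distances(g, algorithm = "dijkstra")
  expect_equal(unname(shortest_path_oracle(net)), unname(ref),
               tolerance = 1e-12)
})

test_that("radiality reproduces forced and hand-computed values", {
  # 2 nodes at any distance d: Crad = (d + 1 - d) / 1 = 1 for both
  m2 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(radiality(build_distance_network(m2))), c(1, 1))

  # profiles A = C = (0,0), B = (3,4): d(A,B) = d(B,C) = 5, d(A,C) = 0
  m3 <- matrix(c(0, 0, 3, 4, 0, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), NULL))
  crad <- radiality(build_distance_network(m3))
  expect_equal(unname(crad), c(3.5, 1.0, 3.5))
  norm <- normalize_radiality(crad)
  expect_equal(unname(norm), c(1.3125, 0.375, 1.3125))
  expect_equal(mean(norm), 1, tolerance = 1e-15)
})

test_that("radiality matches the brute-force re-evaluation on random networks", {
  set.seed(113)
  for (i in 1:10) {
    net <- build_distance_network(random_response_matrix())
    expect_equal(unname(radiality(net)), brute_radiality(net$distances),
                 tolerance = 1e-12)
  }
})

test_that("the node with minimal summed distance attains maximal radiality", {
  set.seed(127)
  for (i in 1:10) {
    net <- build_distance_network(random_response_matrix(15, 4))
    expect_equal(which.max(radiality(net)), which.min(rowSums(net$distances)))
  }
})

test_that("shrinking a node's distance never decreases its radiality", {
  set.seed(131)
  net <- build_distance_network(random_response_matrix(10, 5))
  d <- net$distances
  # pick an off-diagonal pair that does not realize the diameter
  pair <- which(d > 0 & d < net$diameter - 1e-9, arr.ind = TRUE)[1, ]
  before <- radiality(net)[pair[1]]
  d2 <- d
  d2[pair[1], pair[2]] <- d2[pair[2], pair[1]] <- d[pair[1], pair[2]] / 2
  net2 <- as_network(d2)
  net2$diameter <- net$diameter  # diameter held fixed
  after <- (net2$diameter + 1) - rowSums(net2$distances)[pair[1]] / (net2$n_nodes - 1)
  expect_gte(after, before)
})

test_that("normalization and classification invariants hold", {
  set.seed(137)
  raw <- runif(30, 2, 4)
  norm <- normalize_radiality(raw)
  expect_equal(mean(norm), 1, tolerance = 1e-12)
  expect_equal(normalize_radiality(rep(3, 8)), rep(1, 8))
  expect_error(normalize_radiality(c(-1, 1)), "mean radiality is zero")
  # classification invariant under positive rescaling of raw radialities
  for (k in c(0.01, 1, 250)) {
    expect_equal(classify_nodes(normalize_radiality(k * raw)),
                 classify_nodes(norm))
  }
})

test_that("classification uses strict cuts and a zero-spread escape", {
  vals <- c(a = 0.8, b = 1.0, c = 1.2)
  rule <- significance_rule(vals)
  # value placed exactly on the low cut is ns
  vals2 <- c(vals, d = rule$low_cut)
  calls <- classify_nodes(vals2, rule)
  expect_equal(unname(calls["d"]), "ns")
  expect_equal(unname(classify_nodes(c(1, 1, 1, 1))), rep("ns", 4))
})

test_that("sample and population SD conventions scale the spread as expected", {
  v <- c(0.7, 0.9, 1.0, 1.4)
  rs <- significance_rule(v, "sample")
  rp <- significance_rule(v, "population")
  expect_equal(rp$spread, rs$spread * sqrt(3 / 4))
  expect_lt(rp$spread, rs$spread)
})

test_that("node relabeling permutes every output identically", {
  set.seed(139)
  m <- random_response_matrix(12, 5)
  perm <- sample(12)
  t1 <- radiality_table(structure(
    list(network_id = c(group = "primary", depth = "ATL"), nodes = rownames(m),
         replicates = paste0("r", 1:5), values = m, n_replicates = 5,
         n_imputed = 0L, missing_policy = "impute_mean"),
    class = "response_matrix"))
  mp <- m[perm, ]
  t2 <- radiality_table(structure(
    list(network_id = c(group = "primary", depth = "ATL"), nodes = rownames(mp),
         replicates = paste0("r", 1:5), values = mp, n_replicates = 5,
         n_imputed = 0L, missing_policy = "impute_mean"),
    class = "response_matrix"))
  reord <- match(t1$rows$analyte, t2$rows$analyte)
  expect_equal(t2$rows$normalized_radiality[reord], t1$rows$normalized_radiality)
  expect_equal(t2$rows$call[reord], t1$rows$call)
  expect_equal(t2$network_stats$diameter, t1$network_stats$diameter)
})

test_that("degenerate networks are rejected", {
  expect_error(build_distance_network(matrix(1, 1, 3)), "at least 2 nodes")
})
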