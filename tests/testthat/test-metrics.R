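test_that("density thresholding keeps the strongest edges deterministically", {
  set.seed(2)
  n <- 10
  Zp <- matrix(0, n, n)
  w <- runif(45)
  Zp[upper.tri(Zp)] <- w
  Zp <- Zp + t(Zp)
  g <- densityThreshold(Zp, 0.2)
  expect_equal(sum(g@adjacency) / 2, 9)    # ceiling(0.2 * 45)
  kept <- Zp[upper.tri(Zp)][g@adjacency[upper.tri(g@adjacency)] == 1]
  expect_equal(sort(kept), sort(w)[37:45]) # exactly the 9 largest
  # full density on an all-positive matrix gives the complete graph
  full <- densityThreshold(abs(Zp) + 0.01 - diag(diag(abs(Zp) + 0.01)), 1)
  expect_equal(sum(full@adjacency), n * (n - 1))
  # equal weights: deterministic tie-breaking, stable across calls
  ones <- matrix(1, n, n); diag(ones) <- 0
  t1 <- densityThreshold(ones, 0.2)
  t2 <- densityThreshold(ones, 0.2)
  expect_identical(t1@adjacency, t2@adjacency)
  expect_equal(sum(t1@adjacency) / 2, 9)
  # more edges than positive entries -> error
  sparse <- matrix(0, n, n); sparse[1, 2] <- sparse[2, 1] <- 1
  expect_error(densityThreshold(sparse, 0.5), "positive entries")
})

test_that("the density sweep is nested and uses the 16-value default grid", {
  expect_length(defaultDensities(), 16)
  expect_equal(range(defaultDensities()), c(0.10, 0.25))
  Zp <- plantedSubjectMatrix(seed = 55, nVolumes = 100)
  graphs <- thresholdSweep(Zp)
  expect_length(graphs, 16)
  for (i in seq_len(15)) {
    a <- graphs[[i]]@adjacency
    b <- graphs[[i + 1]]@adjacency
    expect_true(all(b[a == 1] == 1))   # edge sets nested
  }
})

test_that("global metrics match closed-form worked cases", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  m <- globalMetrics(asBinaryGraph(k3))
  expect_equal(unname(m["clustering_coefficient"]), 1)
  expect_equal(unname(m["characteristic_path_length"]), 1)
  expect_equal(unname(m["local_efficiency"]), 1)

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  mp <- globalMetrics(asBinaryGraph(p3))
  expect_equal(unname(mp["characteristic_path_length"]), 4 / 3)
  expect_equal(unname(mp["clustering_coefficient"]), 0)

  # two disconnected 4-cliques, clique partition: Q = 2 (0.5 - 0.25) = 0.5
  cl <- matrix(0, 8, 8)
  cl[1:4, 1:4] <- 1; cl[5:8, 5:8] <- 1; diag(cl) <- 0
  mc <- globalMetrics(asBinaryGraph(cl))
  expect_equal(unname(mc["modularity"]), 0.5, tolerance = 1e-12)

  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  ms <- globalMetrics(asBinaryGraph(star))
  expect_equal(unname(ms["assortativity"]), -1, tolerance = 1e-12)
  # regular graph: assortativity undefined -> NA
  expect_true(is.na(globalMetrics(asBinaryGraph(k3))["assortativity"]))
})

test_that("nodal metrics match path-enumeration oracles on named cases", {
  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- star4[2:4, 1] <- 1
  nm <- nodalMetrics(asBinaryGraph(star4))
  expect_equal(nm$degree_centrality, c(3, 1, 1, 1))
  expect_equal(nm$betweenness_centrality, c(3, 0, 0, 0))  # 3 leaf pairs
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(nodalMetrics(asBinaryGraph(k4))$nodal_efficiency, rep(1, 4))
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(nodalMetrics(asBinaryGraph(p3))$nodal_efficiency[1],
               (1 + 0.5) / 2)
})

test_that("all metrics equal brute-force oracles on random connected graphs", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    A <- randomConnectedGraph(n, 0.5, seed = 500 + rep)
    G <- asBinaryGraph(A)
    gm <- globalMetrics(G, seed = rep)
    expect_equal(unname(gm["clustering_coefficient"]),
                 mean(oracleClustering(A)), tolerance = 1e-12)
    expect_equal(unname(gm["characteristic_path_length"]), oracleCpl(A),
                 tolerance = 1e-12)
    expect_equal(unname(gm["local_efficiency"]),
                 mean(oracleLocalEfficiency(A)), tolerance = 1e-12)
    expect_equal(unname(gm["modularity"]), oracleMaxModularity(A, 1),
                 tolerance = 1e-9)
    aOr <- oracleAssortativity(A)
    if (is.finite(aOr)) {
      expect_equal(unname(gm["assortativity"]), aOr, tolerance = 1e-12)
    }
    nm <- nodalMetrics(G)
    expect_equal(nm$degree_centrality, rowSums(A))
    expect_equal(nm$betweenness_centrality, oracleBetweenness(A),
                 tolerance = 1e-9)
    expect_equal(nm$nodal_efficiency, oracleNodalEfficiency(A),
                 tolerance = 1e-12)
    expect_equal(nm$clustering_coefficient, oracleClustering(A),
                 tolerance = 1e-12)
  }
})

test_that("threshold averaging skips undefined values and counts them", {
  expect_equal(averageOverThresholds(c(2, 2, 2))$value, 2)
  expect_equal(averageOverThresholds(c(1, 3))$value, 2)
  av <- averageOverThresholds(c(rep(1, 15), NA))
  expect_equal(av$value, 1)
  expect_equal(av$n, 15L)
  expect_true(is.na(averageOverThresholds(c(NA_real_, NA_real_))$value))
})

test_that("small-world index is ~1 for random graphs, >1 for lattices", {
  set.seed(6)
  # Erdos-Renyi at matched density: sigma near 1
  sig <- vapply(1:5, function(i) {
    g <- igraph::sample_gnp(72, 0.15)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    globalMetrics(asBinaryGraph(A), seed = i)["small_world_index"]
  }, 1.0)
  expect_lt(abs(mean(sig) - 1), 0.15)
  # Watts-Strogatz at low rewiring: strongly small-world
  gw <- igraph::sample_smallworld(1, 72, 5, 0.1)
  Aw <- as.matrix(igraph::as_adjacency_matrix(gw))
  Aw[Aw > 1] <- 1
  sw <- globalMetrics(asBinaryGraph(Aw), seed = 2)["small_world_index"]
  expect_gt(unname(sw), 1)
})

test_that("metric tables average over thresholds and combine hemispheres", {
  Zp <- plantedSubjectMatrix(seed = 91, nVolumes = 100)
  tab <- graphMetricTable(Zp, densities = c(0.15, 0.2), subjectId = "s1",
                          timepointLabel = "12mo", ageDays = 370)
  expect_equal(sum(tab$scope == "global"), 6)
  expect_equal(sum(tab$scope == "node"), 4 * 72)
  nod <- tab[tab$scope == "node", ]
  bil <- suppressWarnings(combineBilateral(nod))
  expect_equal(nrow(bil), 4 * 36)
  # L = 0.2, R = 0.4 -> 0.3
  toy <- data.frame(subject_id = "s", timepoint_label = "12mo",
                    age_days = 1, scope = "node", metric = "m",
                    region = c("r01_L", "r01_R"), value = c(0.2, 0.4),
                    n_thresholds = 2L)
  expect_equal(combineBilateral(toy)$value, 0.3)
  expect_equal(combineBilateral(toy)$region, "r01")
  # unpaired region passes through with a warning
  toy2 <- rbind(toy, within(toy[1, ], { region <- "odd"; value <- 9 }))
  expect_warning(out2 <- combineBilateral(toy2), "unaveraged")
  expect_true("odd" %in% out2$region)
  expect_equal(out2$value[out2$region == "odd"], 9)
})

test_that("clustering rises and path length falls as density grows", {
  # statistical trend over random weight matrices whose lowest-density graph
  # is still connected (path length over connected pairs is only comparable
  # across nested graphs when connectivity holds)
  set.seed(14)
  dcc <- dcpl <- numeric(10)
  for (r in 1:10) {
    n <- 72
    Zp <- matrix(0, n, n)
    Zp[upper.tri(Zp)] <- runif(n * (n - 1) / 2)
    Zp <- Zp + t(Zp)
    graphs <- thresholdSweep(Zp, densities = c(0.10, 0.25))
    expect_true(graphs[[1]]@connected)
    m1 <- globalMetrics(graphs[[1]], seed = r)
    m2 <- globalMetrics(graphs[[2]], seed = r)
    dcc[r] <- m2["clustering_coefficient"] - m1["clustering_coefficient"]
    dcpl[r] <- m2["characteristic_path_length"] -
      m1["characteristic_path_length"]
  }
  expect_true(all(dcpl < 0))    # adding edges shortens connected paths
  expect_gt(mean(dcc), 0)       # denser random graphs cluster more
})
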