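#' BinaryGraph: a density-thresholded binary adjacency matrix
#'
#' @slot adjacency 0/1 symmetric matrix, zero diagonal.
#' @slot density Achieved edge fraction.
#' @slot connected TRUE when the graph has a single connected component.
#' @export
setClass("BinaryGraph",
  representation(adjacency = "matrix", density = "numeric",
                 connected = "logical")
)

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0, 1))) return("adjacency must be 0/1")
  if (any(diag(a) != 0)) return("no self-loops allowed")
  if (max(abs(a - t(a))) > 0) return("adjacency must be symmetric")
  TRUE
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (density %.3f), %sconnected\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              object@density, if (object@connected) "" else "NOT "))
})

.toIgraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G@adjacency, mode = "undirected")
}

#' Density-threshold a non-negative connectivity matrix into a binary graph
#'
#' Retains the `ceiling(density * n(n-1)/2)` strongest unique positive edges.
#' Ties at the cutoff are broken by ascending linear (column-major upper
#' triangle) index, so the edge set is deterministic.
#'
#' @param Zp Non-negative weight matrix (Z+), or a
#'   [ConnectivityMatrix-class].
#' @param density Target edge fraction in (0, 1].
#' @return A [BinaryGraph-class].
#' @export
densityThreshold <- function(Zp, density) {
  if (is(Zp, "ConnectivityMatrix")) Zp <- connValues(positivePart(Zp))
  .check(density > 0 && density <= 1, "density: must lie in (0, 1]")
  .check(all(Zp >= 0), "Zp: must be non-negative (use positivePart first)")
  n <- nrow(Zp)
  emax <- n * (n - 1) / 2
  nEdges <- ceiling(density * emax)
  w <- Zp[upper.tri(Zp)]
  pos <- which(w > 0)
  if (nEdges > length(pos)) {
    stop(sprintf(
      "density %.3f requests %d edges but only %d positive entries available",
      density, nEdges, length(pos)), call. = FALSE)
  }
  ord <- pos[order(-w[pos], pos)]
  keep <- ord[seq_len(nEdges)]
  a <- matrix(0, n, n, dimnames = dimnames(Zp))
  ut <- which(upper.tri(a))
  a[ut[keep]] <- 1
  a <- a + t(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  conn <- igraph::is_connected(g)
  new("BinaryGraph", adjacency = a, density = nEdges / emax, connected = conn)
}

#' Default density grid
#'
#' 16 evenly spaced densities from 0.10 to 0.25. (A grid honoring both a
#' 16-value count and those endpoints implies a step of 0.01.)
#'
#' @return Numeric vector of length 16.
#' @export
defaultDensities <- function() seq(0.10, 0.25, length.out = 16)

#' Threshold a matrix over a density sweep
#'
#' @inheritParams densityThreshold
#' @param densities Ascending density grid (default [defaultDensities()]).
#' @return List of [BinaryGraph-class], one per density; edge sets are nested
#'   (each lower-density edge set is a prefix of the next).
#' @export
thresholdSweep <- function(Zp, densities = defaultDensities()) {
  .check(all(diff(densities) > 0), "densities: must be ascending")
  lapply(densities, function(d) densityThreshold(Zp, d))
}

.nodalClustering <- function(g) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  cc
}

.nodalEfficiency <- function(g) {
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  rowSums(inv) / (igraph::vcount(g) - 1)
}

.localEfficiency <- function(g) {
  n <- igraph::vcount(g)
  vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    k <- length(nb)
    if (k < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub)
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    sum(inv) / (k * (k - 1))
  }, 1.0)
}

#' Global graph metrics of a binary graph
#'
#' Six metrics: mean nodal clustering coefficient, characteristic path length
#' (mean shortest path over connected ordered pairs; disconnection is
#' tolerated and flagged by the graph's `connected` slot), local efficiency,
#' small-world index sigma = (C/C_rand)/(L/L_rand) against degree-preserving
#' rewired null graphs, modularity (best of `nRestarts` Louvain runs at
#' gamma = 1), and degree assortativity. Metrics that are undefined on a
#' given graph (e.g. assortativity with zero degree variance, or sigma when
#' the rewired null has zero clustering) are returned as `NA`.
#'
#' @param G A [BinaryGraph-class].
#' @param nRewires Number of rewired null graphs for sigma (default 10).
#' @param nRestarts Louvain restarts for the modularity metric (default 10).
#' @param seed Seed for the null model and Louvain restarts.
#' @return Named numeric vector: clustering_coefficient,
#'   characteristic_path_length, local_efficiency, small_world_index,
#'   modularity, assortativity.
#' @export
globalMetrics <- function(G, nRewires = 10L, nRestarts = 10L, seed = 1L) {
  g <- .toIgraph(G)
  n <- igraph::vcount(g)
  cc <- mean(.nodalClustering(g))
  cpl <- igraph::mean_distance(g, unconnected = TRUE)
  leff <- mean(.localEfficiency(g))
  amix <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(amix)) amix <- NA_real_

  # restart 1 from singletons, later restarts from random initial partitions
  # so the restarts explore different basins of the Q landscape
  qBest <- max(vapply(seq_len(nRestarts), function(i) {
    ini <- if (i == 1) NULL else .withSeed(deriveSeed(seed, 6L, i), {
      sample.int(max(2L, n %/% 2L), n, replace = TRUE)
    })
    louvainOnce(G@adjacency, gamma = 1, seed = deriveSeed(seed, 7L, i),
                init = ini)@modularityQ
  }, 1.0))

  # degree-preserving double-edge-swap null
  sigma <- NA_real_
  cr <- lr <- numeric(nRewires)
  .withSeed(deriveSeed(seed, 8L), {
    for (i in seq_len(nRewires)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = max(10L * igraph::ecount(g), 1L)))
      cr[i] <- mean(.nodalClustering(gr))
      lr[i] <- igraph::mean_distance(gr, unconnected = TRUE)
    }
  })
  cRand <- mean(cr)
  lRand <- mean(lr)
  if (is.finite(cRand) && cRand > 0 && is.finite(lRand) && lRand > 0 &&
      is.finite(cpl)) {
    sigma <- (cc / cRand) / (cpl / lRand)
  }
  c(clustering_coefficient = cc,
    characteristic_path_length = if (is.finite(cpl)) cpl else NA_real_,
    local_efficiency = leff,
    small_world_index = sigma,
    modularity = qBest,
    assortativity = amix)
}

#' Nodal graph metrics of a binary graph
#'
#' Four per-node metrics: degree centrality (neighbor count), betweenness
#' centrality (Brandes pair dependencies, unnormalized, endpoints excluded),
#' nodal efficiency (mean inverse shortest-path distance to all other nodes,
#' with 1/Inf = 0), and the clustering coefficient
#' (triangles / (deg (deg - 1) / 2), 0 when degree < 2).
#'
#' @param G A [BinaryGraph-class].
#' @return data.frame: node, degree_centrality, betweenness_centrality,
#'   nodal_efficiency, clustering_coefficient.
#' @export
nodalMetrics <- function(G) {
  g <- .toIgraph(G)
  nm <- rownames(G@adjacency) %||% sprintf("node_%02d", seq_len(nrow(G@adjacency)))
  data.frame(
    node = nm,
    degree_centrality = as.numeric(igraph::degree(g)),
    betweenness_centrality = as.numeric(igraph::betweenness(g, normalized = FALSE)),
    nodal_efficiency = .nodalEfficiency(g),
    clustering_coefficient = .nodalClustering(g),
    stringsAsFactors = FALSE)
}

#' Average a metric over the density sweep
#'
#' Arithmetic mean over the densities at which the metric is defined; the
#' count of contributing thresholds is recorded.
#'
#' @param values Numeric vector of per-density values (NA = undefined).
#' @return List: `value` (NA when all are undefined), `n` thresholds used.
#' @export
averageOverThresholds <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) return(list(value = NA_real_, n = 0L))
  list(value = mean(values[ok]), n = sum(ok))
}

#' Threshold-averaged global and nodal metrics for one subject matrix
#'
#' Runs the density sweep and averages each metric over the thresholds at
#' which it is defined.
#'
#' @inheritParams thresholdSweep
#' @param subjectId,timepointLabel,ageDays Identifiers copied to the rows.
#' @param seed Seed for the stochastic metrics (null models, Louvain
#'   restarts).
#' @return Long data.frame (MetricTable rows): subject_id, timepoint_label,
#'   age_days, scope ("global"/"node"), metric, region, value, n_thresholds.
#' @export
graphMetricTable <- function(Zp, densities = defaultDensities(),
                             subjectId = NA_character_,
                             timepointLabel = NA_character_,
                             ageDays = NA_real_, seed = 1L) {
  if (is(Zp, "ConnectivityMatrix")) {
    if (is.na(subjectId)) subjectId <- Zp@subjectId
    if (is.na(timepointLabel)) timepointLabel <- Zp@timepointLabel
    Zp <- connValues(positivePart(Zp))
  }
  graphs <- thresholdSweep(Zp, densities)
  glb <- vapply(seq_along(graphs), function(i) {
    globalMetrics(graphs[[i]], seed = deriveSeed(seed, i))
  }, numeric(6))
  gRows <- do.call(rbind, lapply(rownames(glb), function(mname) {
    av <- averageOverThresholds(glb[mname, ])
    data.frame(subject_id = subjectId, timepoint_label = timepointLabel,
               age_days = ageDays, scope = "global", metric = mname,
               region = NA_character_, value = av$value,
               n_thresholds = av$n, stringsAsFactors = FALSE)
  }))
  nod <- lapply(graphs, nodalMetrics)
  metrics <- c("degree_centrality", "betweenness_centrality",
               "nodal_efficiency", "clustering_coefficient")
  nRows <- do.call(rbind, lapply(metrics, function(mname) {
    vals <- vapply(nod, function(d) d[[mname]], numeric(nrow(nod[[1]])))
    data.frame(subject_id = subjectId, timepoint_label = timepointLabel,
               age_days = ageDays, scope = "node", metric = mname,
               region = nod[[1]]$node, value = rowMeans(vals),
               n_thresholds = length(graphs), stringsAsFactors = FALSE)
  }))
  rbind(gRows, nRows)
}

#' Metric table for a whole cohort
#'
#' @param matrices Named list of [ConnectivityMatrix-class] keyed
#'   `subject_timepoint`.
#' @param cohort Cohort design data.frame.
#' @param densities Density grid.
#' @param seed Master seed for the stochastic metrics.
#' @return Long MetricTable data.frame over all subjects and time points.
#' @export
cohortMetricTable <- function(matrices, cohort,
                              densities = defaultDensities(), seed = 1L) {
  meta <- unique(cohort[, c("subject_id", "timepoint_label", "age_days")])
  key <- paste(meta$subject_id, meta$timepoint_label, sep = "_")
  out <- lapply(seq_len(nrow(meta)), function(i) {
    Z <- matrices[[key[i]]]
    if (is.null(Z)) return(NULL)
    graphMetricTable(Z, densities, subjectId = meta$subject_id[i],
                     timepointLabel = meta$timepoint_label[i],
                     ageDays = meta$age_days[i],
                     seed = deriveSeed(seed, 11L, i))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combine left and right hemisphere values per region
#'
#' Nodal rows whose region names end in `_L` / `_R` are averaged into one row
#' per bilateral region (suffix stripped); unpaired regions are passed
#' through unchanged with a warning.
#'
#' @param table A nodal MetricTable (long format, `scope == "node"`).
#' @return The table with bilateral regions averaged.
#' @export
combineBilateral <- function(table) {
  stopifnot(all(table$scope == "node"))
  base <- sub("_[LR]$", "", table$region)
  paired <- grepl("_[LR]$", table$region)
  if (any(!paired)) {
    warning(sum(!paired), " row(s) without an _L/_R suffix passed through unaveraged")
  }
  key <- paste(table$subject_id, table$timepoint_label, table$metric, base)
  out <- do.call(rbind, lapply(split(table, key), function(d) {
    r <- d[1, ]
    r$region <- sub("_[LR]$", "", r$region)
    r$value <- mean(d$value)
    r
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$timepoint_label, out$metric, out$region), ]
}
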