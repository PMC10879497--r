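# Brute-force oracles, independent of the package implementation.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
oracleDistances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracleCpl <- function(A) {
  d <- oracleDistances(A)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) return(NA_real_)
  mean(fin)
}

oracleNodalEfficiency <- function(A) {
  d <- oracleDistances(A)
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n - 1)
  })
}

oracleClustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(A[nb, nb]) / 2
    tri / (k * (k - 1) / 2)
  })
}

oracleLocalEfficiency <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    d <- oracleDistances(sub)
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (k * (k - 1))
  })
}

# all shortest paths between s and t, by recursive enumeration
.allShortestPaths <- function(A, d, s, t) {
  if (s == t) return(list(t))
  if (!is.finite(d[s, t])) return(list())
  out <- list()
  for (u in which(A[s, ] == 1)) {
    if (d[u, t] == d[s, t] - 1) {
      for (p in .allShortestPaths(A, d, u, t)) {
        out[[length(out) + 1L]] <- c(s, p)
      }
    }
  }
  out
}

# betweenness by explicit path enumeration (unnormalized, endpoints excluded,
# each unordered pair counted once)
oracleBetweenness <- function(A) {
  n <- nrow(A)
  d <- oracleDistances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- .allShortestPaths(A, d, s, t)
      if (!length(paths)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        onPath <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + onPath / length(paths)
      }
    }
  }
  b
}

oracleAssortativity <- function(A) {
  deg <- rowSums(A)
  ij <- which(A == 1, arr.ind = TRUE)   # both directions
  suppressWarnings(stats::cor(deg[ij[, 1]], deg[ij[, 2]]))
}

# enumerate all set partitions of 1..n (restricted growth strings)
allSetPartitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum of Q(gamma) over all partitions (includes the i == j
# null term, matching the package convention)
oracleMaxModularity <- function(W, gamma = 1) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  qOf <- function(labels) {
    delta <- outer(labels, labels, `==`)
    sum((W - gamma * outer(k, k) / two_m) * delta) / two_m
  }
  max(vapply(allSetPartitions(n), qOf, 1.0))
}

# direct contingency-table NMI (arithmetic normalization)
oracleNmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pa); hb <- h(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

# BH q-values by the step-up definition: q_(i) = min_{j >= i} m p_(j) / j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sample KS statistic by ECDF evaluation on the pooled support
oracleKs <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- sapply(grid, function(x) mean(a <= x))
  fb <- sapply(grid, function(x) mean(b <= x))
  max(abs(fa - fb))
}

# random connected 0/1 graph (rejection sampling)
randomConnectedGraph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    d <- oracleDistances(A)
    if (all(is.finite(d))) return(A)
  }
}

# all connected labeled graphs on n nodes (n small), as adjacency matrices
allConnectedGraphs <- function(n) {
  ne <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  out <- list()
  for (mask in seq_len(2^ne) - 1L) {
    bits <- as.integer(intToBits(mask))[seq_len(ne)]
    if (sum(bits) < n - 1) next        # too few edges to be connected
    A <- matrix(0, n, n)
    A[ut] <- bits
    A <- A + t(A)
    if (all(is.finite(oracleDistances(A)))) out[[length(out) + 1L]] <- A
  }
  out
}

# shared fixture: one synthetic subject's positive-z connectivity, with
# bilateral ROI names (consecutive L/R pairs)
plantedSubjectMatrix <- function(seed, nVolumes = 415, withinR = 0.5,
                                 betweenR = 0.1, labels = rep(1:6, each = 12)) {
  tgt <- targetCorrelationMatrix(labels, withinR, betweenR)
  ts <- simulateTimeseries(tgt, nVolumes, seed)
  n <- nrow(ts)
  rownames(ts) <- sprintf("r%02d_%s", rep(seq_len(n / 2), each = 2),
                          rep(c("L", "R"), n / 2))
  connValues(positivePart(fisherZ(pearsonMatrix(ts))))
}

asBinaryGraph <- function(A) {
  new("BinaryGraph", adjacency = A,
      density = sum(A) / (nrow(A) * (nrow(A) - 1)),
      connected = all(is.finite(oracleDistances(A))))
}
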