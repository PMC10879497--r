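#' Agreement matrix over repeated partitions
#'
#' `D[i, j]` is the fraction of repetitions in which nodes i and j were
#' assigned to the same module; the diagonal is 1.
#'
#' @param partitions Non-empty list of [Partition-class] over the same node
#'   set.
#' @return An [AgreementMatrix-class].
#' @export
agreementMatrix <- function(partitions) {
  .check(length(partitions) >= 1, "partitions: empty list")
  n <- length(partitions[[1]]@labels)
  labs <- t(vapply(partitions, function(p) {
    .check(length(p@labels) == n, "partitions: node sets differ")
    p@labels
  }, integer(n)))
  D <- .agreement_cpp(labs)
  nm <- partitions[[1]]@nodeNames
  if (length(nm)) dimnames(D) <- list(nm, nm)
  new("AgreementMatrix", values = D, nRepetitions = length(partitions))
}

# subtract the permutation-null expected co-assignment (mean off-diagonal
# agreement) and floor at zero; standard consensus-clustering practice
.nullCorrect <- function(D) {
  off <- D[upper.tri(D)]
  D2 <- pmax(D - mean(off), 0)
  diag(D2) <- 0
  D2
}

.allAgree <- function(partitions) {
  ref <- .canonicalLabels(partitions[[1]]@labels)
  for (p in partitions[-1]) {
    if (!identical(.canonicalLabels(p@labels), ref)) return(FALSE)
  }
  TRUE
}

#' Consensus partition of an agreement matrix
#'
#' Iteratively re-clusters the agreement matrix (after null correction:
#' the mean off-diagonal co-assignment is subtracted and negatives floored
#' at zero) with repeated Louvain runs until all repetitions agree on a
#' single partition. Modules of the returned partition are numbered by
#' descending size (ties by lowest contained node index).
#'
#' @param D An [AgreementMatrix-class].
#' @param gamma Resolution parameter used for the re-clustering.
#' @param seed Integer seed.
#' @param nReps Repetitions per iteration (default 100).
#' @param maxIter Iteration cap (default 50).
#' @param level Level tag for the returned [Partition-class].
#' @return A [Partition-class].
#' @export
consensusPartition <- function(D, gamma = 1, seed = 1L, nReps = 100L,
                               maxIter = 50L, level = "subject-consensus") {
  .check(is(D, "AgreementMatrix"), "D: must be an AgreementMatrix")
  Dv <- agreementValues(D)
  for (it in seq_len(maxIter)) {
    W <- .nullCorrect(Dv)
    if (sum(W) <= 0) {
      # degenerate: all co-assignment at the null level; everything is one block
      lab <- rep(1L, nrow(Dv))
      return(partition(lab, gamma = gamma, level = level,
                       nodeNames = rownames(Dv) %||% character()))
    }
    reps <- repeatedPartitions(W, gamma = gamma, nReps = nReps,
                               seed = deriveSeed(seed, it))
    if (.allAgree(reps)) {
      lab <- .sortedLabels(reps[[1]]@labels)
      return(partition(lab, gamma = gamma, level = level,
                       modularityQ = reps[[1]]@modularityQ,
                       nodeNames = rownames(Dv) %||% character()))
    }
    Dv <- agreementValues(agreementMatrix(reps))
  }
  stop(sprintf(
    "consensus did not converge within %d iterations (gamma = %.2f, %d nodes)",
    maxIter, gamma, nrow(Dv)), call. = FALSE)
}

#' Subject-level consensus partition from a connectivity matrix
#'
#' Runs `nReps` fine-tuned Louvain repetitions on the positive connectivity
#' weights, forms the agreement matrix, and re-clusters it to convergence.
#'
#' @param W Non-negative weight matrix (a subject's Z+ values).
#' @param gamma Resolution parameter.
#' @param nReps Repetitions (the reference analysis used 1000; smaller values
#'   are adequate for strongly modular data).
#' @param seed Integer seed.
#' @return List: `partition` (subject consensus), `reps` (the single-run
#'   partitions), `agreement` (the [AgreementMatrix-class]).
#' @export
subjectConsensus <- function(W, gamma = 1, nReps = 1000L, seed = 1L) {
  if (is(W, "ConnectivityMatrix")) W <- connValues(positivePart(W))
  reps <- repeatedPartitions(W, gamma = gamma, nReps = nReps, seed = seed)
  D <- agreementMatrix(reps)
  part <- consensusPartition(D, gamma = gamma, seed = deriveSeed(seed, 0L),
                             nReps = min(nReps, 100L),
                             level = "subject-consensus")
  list(partition = part, reps = reps, agreement = D)
}

#' Group-level consensus over subject partitions
#'
#' Agreement over the subject-specific consensus partitions, re-clustered to
#' convergence.
#'
#' @param subjectPartitions List of >= 2 [Partition-class].
#' @param gamma Resolution parameter.
#' @param seed Integer seed.
#' @param nReps Repetitions per consensus iteration.
#' @return A [Partition-class] with level "group-consensus".
#' @export
groupConsensus <- function(subjectPartitions, gamma = 1, seed = 1L,
                           nReps = 100L) {
  .check(length(subjectPartitions) >= 2, "subjectPartitions: need >= 2 subjects")
  D <- agreementMatrix(subjectPartitions)
  consensusPartition(D, gamma = gamma, seed = seed, nReps = nReps,
                     level = "group-consensus")
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(p1; p2) / (H(p1) + H(p2))` (arithmetic-mean normalization);
#' equals 1 iff the partitions are identical up to relabeling. When both
#' partitions have zero entropy (single module each) the value is defined as
#' 1; when exactly one has zero entropy it is 0.
#'
#' @param p1,p2 [Partition-class] objects (or integer label vectors) over the
#'   same node set.
#' @return Value in [0, 1].
#' @export
nmi <- function(p1, p2) {
  l1 <- if (is(p1, "Partition")) p1@labels else as.integer(p1)
  l2 <- if (is(p2, "Partition")) p2@labels else as.integer(p2)
  .check(length(l1) == length(l2), "partitions: node sets differ")
  n <- length(l1)
  tab <- table(l1, l2)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  2 * mi / (h1 + h2)
}

#' Sweep the resolution parameter and select the most representative gamma
#'
#' For each gamma in the grid: subject-level consensus partitions for every
#' subject, then a group-level consensus. The selected gamma maximizes the
#' mean NMI between its group partition and the group partitions of all the
#' other gammas (ties broken toward smaller gamma).
#'
#' @param subjectMatrices List of >= 2 non-negative weight matrices (Z+), or
#'   [ConnectivityMatrix-class] objects.
#' @param gammas Resolution grid (default `seq(1, 2, by = 0.1)`).
#' @param nReps Louvain repetitions per subject (default 1000).
#' @param seed Integer master seed.
#' @return List of class `GammaSweepResult`: `gammas`, `partitions` (group
#'   consensus per gamma), `nmiTable`, `meanNmi`, `selectedGamma`,
#'   `selectedPartition`, `subjectPartitions` (for the selected gamma).
#' @export
gammaSweep <- function(subjectMatrices, gammas = seq(1, 2, by = 0.1),
                       nReps = 1000L, seed = 1L) {
  .check(length(subjectMatrices) >= 2, "subjectMatrices: need >= 2 subjects")
  mats <- lapply(subjectMatrices, function(W) {
    if (is(W, "ConnectivityMatrix")) connValues(positivePart(W)) else W
  })
  groupParts <- vector("list", length(gammas))
  subjParts <- vector("list", length(gammas))
  ok <- logical(length(gammas))
  for (g in seq_along(gammas)) {
    res <- tryCatch({
      sp <- lapply(seq_along(mats), function(s) {
        subjectConsensus(mats[[s]], gamma = gammas[g], nReps = nReps,
                         seed = deriveSeed(seed, g, s))$partition
      })
      gp <- groupConsensus(sp, gamma = gammas[g],
                           seed = deriveSeed(seed, g, 0L))
      list(sp = sp, gp = gp)
    }, error = function(e) {
      warning(sprintf("gamma %.2f skipped: %s", gammas[g], conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      ok[g] <- TRUE
      groupParts[[g]] <- res$gp
      subjParts[[g]] <- res$sp
    }
  }
  .check(sum(ok) >= 2, "gammas: fewer than 2 sweep points converged")
  idx <- which(ok)
  k <- length(idx)
  nmiTab <- matrix(NA_real_, length(gammas), length(gammas),
                   dimnames = list(gammas, gammas))
  for (a in idx) for (b in idx) {
    nmiTab[a, b] <- if (a == b) 1 else nmi(groupParts[[a]], groupParts[[b]])
  }
  meanNmi <- rep(NA_real_, length(gammas))
  for (a in idx) meanNmi[a] <- mean(nmiTab[a, setdiff(idx, a)])
  sel <- idx[which.max(meanNmi[idx])]   # which.max takes the first tie
  structure(list(gammas = gammas, converged = ok, partitions = groupParts,
                 nmiTable = nmiTab, meanNmi = meanNmi,
                 selectedGamma = gammas[sel],
                 selectedPartition = groupParts[[sel]],
                 subjectPartitions = subjParts[[sel]]),
            class = "GammaSweepResult")
}

#' @export
print.GammaSweepResult <- function(x, ...) {
  cat("Resolution sweep:", paste(x$gammas, collapse = ", "), "\n")
  cat(sprintf("selected gamma = %.2f (%d modules, mean NMI %.3f)\n",
              x$selectedGamma, nModules(x$selectedPartition),
              max(x$meanNmi, na.rm = TRUE)))
  invisible(x)
}

# ---- Hungarian assignment (shortest augmenting path, O(k^3)) ----
# cost: square matrix; returns assign[i] = column matched to row i.
# Rows/columns are 0-indexed internally with a virtual row/column 0; R
# indices carry a +1 offset throughout.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)       # row potentials, u[i + 1]
  v <- numeric(n + 1)       # column potentials, v[j + 1]
  p <- integer(n + 1)       # p[j + 1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

# match modules of `labels` onto modules of `ref` by maximal overlap
# (Hungarian on the negated contingency table); returns the mapped labels.
.matchLabels <- function(labels, ref) {
  k1 <- max(labels)
  k2 <- max(ref)
  k <- max(k1, k2)
  tab <- matrix(0, k, k)
  t0 <- table(factor(labels, levels = seq_len(k)),
              factor(ref, levels = seq_len(k)))
  tab[] <- as.numeric(t0)
  map <- .hungarian(-tab)
  map[labels]
}

#' Per-node classification consistency against a consensus partition
#'
#' For each repetition, rep modules are matched to consensus modules by
#' maximal overlap (Hungarian assignment on the contingency table); a node
#' counts as correctly assigned when its rep module maps onto its consensus
#' module. Returns the fraction of repetitions in which each node was
#' correctly assigned.
#'
#' @param reps List of [Partition-class] repetitions.
#' @param consensus The consensus [Partition-class].
#' @return Named numeric vector of per-node fractions in [0, 1].
#' @export
classificationConsistency <- function(reps, consensus) {
  ref <- consensus@labels
  n <- length(ref)
  correct <- numeric(n)
  for (p in reps) {
    .check(length(p@labels) == n, "reps: node sets differ")
    mapped <- .matchLabels(p@labels, ref)
    correct <- correct + (mapped == ref)
  }
  out <- correct / length(reps)
  if (length(consensus@nodeNames)) names(out) <- consensus@nodeNames
  out
}

#' Mean classification consistency per module
#'
#' Used to rank modules by reliability; the "first" modules of an analysis
#' are those whose nodes are most consistently assigned.
#'
#' @inheritParams classificationConsistency
#' @return Numeric vector, one mean consistency per module id.
#' @export
moduleConsistency <- function(reps, consensus) {
  cc <- classificationConsistency(reps, consensus)
  as.numeric(tapply(cc, consensus@labels, mean))
}

#' Select the most reliable modules
#'
#' Returns the ids of the `k` modules with the highest mean classification
#' consistency (ties toward the lower module id, i.e. the larger module under
#' the package's size-ordered numbering).
#'
#' @inheritParams classificationConsistency
#' @param k Number of modules to select (default 3).
#' @return Integer vector of module ids.
#' @export
selectReliableModules <- function(reps, consensus, k = 3L) {
  mc <- moduleConsistency(reps, consensus)
  .check(k <= length(mc), "k: more modules requested than present")
  order(-mc, seq_along(mc))[seq_len(k)]
}

#' Module correspondence across time points
#'
#' For each pair of consecutive time points, tabulates how nodes flow between
#' modules and identifies the dominant correspondence of each source module
#' by maximal Jaccard overlap.
#'
#' @param partitionsByTimepoint Named list of >= 2 [Partition-class] over the
#'   same node set, in chronological order.
#' @return List: `flows` — data.frame (timepoint_from, timepoint_to,
#'   module_from, module_to, n_shared_nodes, jaccard); `dominant` — the rows
#'   with maximal Jaccard per (timepoint_from, module_from).
#' @export
matchModulesAcrossTimepoints <- function(partitionsByTimepoint) {
  .check(length(partitionsByTimepoint) >= 2,
         "partitionsByTimepoint: need >= 2 time points")
  nms <- names(partitionsByTimepoint) %||%
    as.character(seq_along(partitionsByTimepoint))
  rows <- list()
  for (t in seq_len(length(partitionsByTimepoint) - 1L)) {
    a <- partitionsByTimepoint[[t]]@labels
    b <- partitionsByTimepoint[[t + 1L]]@labels
    .check(length(a) == length(b), "partitions: node sets differ")
    tab <- table(a, b)
    for (ma in seq_len(nrow(tab))) for (mb in seq_len(ncol(tab))) {
      shared <- tab[ma, mb]
      if (shared == 0) next
      un <- sum(a == ma) + sum(b == mb) - shared
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint_from = nms[t], timepoint_to = nms[t + 1L],
        module_from = as.integer(rownames(tab)[ma]),
        module_to = as.integer(colnames(tab)[mb]),
        n_shared_nodes = as.integer(shared),
        jaccard = as.numeric(shared) / un,
        stringsAsFactors = FALSE)
    }
  }
  flows <- do.call(rbind, rows)
  keyF <- paste(flows$timepoint_from, flows$module_from)
  dominant <- do.call(rbind, lapply(split(flows, keyF), function(d) {
    d[which.max(d$jaccard), ]
  }))
  rownames(dominant) <- NULL
  list(flows = flows, dominant = dominant)
}
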