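#' One fine-tuned Louvain run
#'
#' Greedy two-phase Louvain maximizing the resolution-adjusted quality
#' \deqn{Q(\gamma) = \frac{1}{2m}\sum_{ij}\left[W_{ij} - \gamma
#'   \frac{k_i k_j}{2m}\right]\delta(c_i, c_j)}
#' followed by an iterative single-node fine-tuning pass on the original
#' graph. The node sweep order is randomized by `seed`.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal and at
#'   least one positive edge.
#' @param gamma Resolution parameter (> 0); larger values favor smaller
#'   modules.
#' @param seed Integer seed for the sweep order.
#' @param finetune Apply the fine-tuning pass (default TRUE).
#' @param init Optional initial module labels (default: every node starts as
#'   its own singleton). Random initial partitions diversify restarts when
#'   hunting the maximal-Q partition.
#' @return A [Partition-class] with `modularityQ` set.
#' @export
louvainOnce <- function(W, gamma = 1, seed = 1L, finetune = TRUE,
                        init = NULL) {
  .checkWeightMatrix(W)
  if (!is.null(init)) {
    .check(length(init) == nrow(W), "init: wrong length")
    init <- as.integer(init)
  }
  res <- .louvain_cpp(W, gamma, as.integer(seed), finetune, init)
  partition(res$labels, gamma = gamma, level = "single-run",
            modularityQ = res$q, nodeNames = rownames(W) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkWeightMatrix <- function(W) {
  .check(is.matrix(W) && nrow(W) == ncol(W), "W: must be a square matrix")
  .check(max(abs(W - t(W))) <= 1e-12, "W: must be symmetric")
  .check(all(W >= 0), "W: must be non-negative")
  .check(all(diag(W) == 0), "W: diagonal must be zero")
  if (sum(W) <= 0) stop("empty graph: matrix has no positive edge weight",
                        call. = FALSE)
  invisible(TRUE)
}

#' Fine-tune a partition by single-node reassignment
#'
#' Repeatedly moves single nodes to the neighboring community with maximal
#' quality gain until no move improves Q. The output Q is never below the
#' input Q.
#'
#' @inheritParams louvainOnce
#' @param part A [Partition-class] of `W`'s nodes.
#' @return A [Partition-class] with `modularityQ` set.
#' @export
fineTune <- function(W, part, gamma = part@gamma) {
  .checkWeightMatrix(W)
  .check(length(part@labels) == nrow(W), "part: wrong number of nodes")
  res <- .finetune_cpp(W, part@labels, gamma)
  partition(res$labels, gamma = gamma, level = part@level,
            modularityQ = res$q, nodeNames = part@nodeNames)
}

#' Resolution-adjusted modularity of a given partition
#'
#' @inheritParams louvainOnce
#' @param labels Integer module labels (or a [Partition-class]).
#' @return The quality value Q(gamma).
#' @export
modularityScore <- function(W, labels, gamma = 1) {
  if (is(labels, "Partition")) labels <- labels@labels
  .checkWeightMatrix(W)
  .modularity_q_cpp(W, as.integer(labels), gamma)
}

#' Repeated seeded Louvain runs
#'
#' `nReps` independent fine-tuned Louvain runs whose per-repetition seeds are
#' derived from the master `seed`, so the whole list is reproducible.
#'
#' @inheritParams louvainOnce
#' @param nReps Number of repetitions (>= 1).
#' @return List of [Partition-class] objects.
#' @export
repeatedPartitions <- function(W, gamma = 1, nReps = 1000L, seed = 1L) {
  .check(nReps >= 1, "nReps: must be >= 1")
  .checkWeightMatrix(W)
  seeds <- vapply(seq_len(nReps), function(i) deriveSeed(seed, i), 1L)
  res <- .repeated_louvain_cpp(W, gamma, seeds)
  lapply(seq_len(nReps), function(i) {
    partition(res$labels[i, ], gamma = gamma, level = "single-run",
              modularityQ = res$q[i],
              nodeNames = rownames(W) %||% character())
  })
}
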