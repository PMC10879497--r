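#' ConnectivityMatrix: a subject-level Fisher-z connectivity matrix
#'
#' Symmetric ROI-by-ROI matrix of Fisher z-transformed Pearson correlations
#' (the matrix usually written Z; its non-negative part Z+ is obtained with
#' [positivePart()]). The diagonal is stored as zero and excluded from all
#' statistics.
#'
#' @slot values Numeric n x n matrix, symmetric, zero diagonal, finite.
#' @slot roiNames Character vector of ROI labels, length n.
#' @slot subjectId Subject identifier.
#' @slot timepointLabel Time-point label (e.g. "12mo").
#' @slot nSessionsAveraged Number of sessions averaged into this matrix.
#' @export
setClass("ConnectivityMatrix",
  representation(
    values = "matrix",
    roiNames = "character",
    subjectId = "character",
    timepointLabel = "character",
    nSessionsAveraged = "integer"
  ),
  prototype(subjectId = NA_character_, timepointLabel = NA_character_,
            nSessionsAveraged = 1L)
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (length(object@roiNames) != nrow(v)) {
    return("roiNames length must match matrix dimension")
  }
  if (anyDuplicated(object@roiNames)) return("duplicate ROI names")
  if (!all(is.finite(v))) return("non-finite entries in values")
  if (max(abs(v - t(v))) > 1e-12) return("values not symmetric (tol 1e-12)")
  if (any(diag(v) != 0)) return("diagonal must be stored as 0")
  TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param roiNames ROI labels; defaults to rownames or `roi_1..n`.
#' @param subjectId,timepointLabel Optional identifiers.
#' @param nSessionsAveraged Number of sessions averaged (default 1).
#' @return A [ConnectivityMatrix-class] object.
#' @export
connectivityMatrix <- function(values, roiNames = NULL,
                               subjectId = NA_character_,
                               timepointLabel = NA_character_,
                               nSessionsAveraged = 1L) {
  if (is.null(roiNames)) {
    roiNames <- rownames(values)
    if (is.null(roiNames)) {
      roiNames <- sprintf("roi_%02d", seq_len(nrow(values)))
    }
  }
  dimnames(values) <- list(roiNames, roiNames)
  new("ConnectivityMatrix", values = values, roiNames = roiNames,
      subjectId = as.character(subjectId),
      timepointLabel = as.character(timepointLabel),
      nSessionsAveraged = as.integer(nSessionsAveraged))
}

#' Partition: a module assignment of network nodes
#'
#' @slot labels Integer module id per node, contiguous from 1.
#' @slot gamma Resolution parameter used to obtain the partition.
#' @slot level One of "single-run", "subject-consensus", "group-consensus".
#' @slot modularityQ Value of the resolution-adjusted quality function.
#' @slot nodeNames Node labels (may be empty).
#' @export
setClass("Partition",
  representation(
    labels = "integer",
    gamma = "numeric",
    level = "character",
    modularityQ = "numeric",
    nodeNames = "character"
  ),
  prototype(gamma = 1, level = "single-run", modularityQ = NA_real_,
            nodeNames = character())
)

setValidity("Partition", function(object) {
  l <- object@labels
  if (length(l) == 0) return("empty partition")
  if (anyNA(l)) return("NA labels")
  k <- max(l)
  if (min(l) != 1L || !all(seq_len(k) %in% l)) {
    return("labels must be contiguous integers starting at 1")
  }
  if (length(object@nodeNames) &&
      length(object@nodeNames) != length(l)) {
    return("nodeNames length must match labels")
  }
  if (!object@level %in% c("single-run", "subject-consensus",
                           "group-consensus")) {
    return("invalid level")
  }
  TRUE
})

#' Construct a Partition
#'
#' @param labels Integer-like module ids (relabeled contiguously from 1,
#'   preserving order of first appearance).
#' @param gamma Resolution parameter (default 1).
#' @param level Provenance level of the partition.
#' @param modularityQ Quality-function value, if known.
#' @param nodeNames Optional node labels.
#' @return A [Partition-class] object.
#' @export
partition <- function(labels, gamma = 1, level = "single-run",
                      modularityQ = NA_real_, nodeNames = character()) {
  labels <- .canonicalLabels(as.integer(labels))
  new("Partition", labels = labels, gamma = as.numeric(gamma),
      level = level, modularityQ = as.numeric(modularityQ),
      nodeNames = as.character(nodeNames))
}

#' AgreementMatrix: co-assignment fractions across repeated partitions
#'
#' @slot values Symmetric n x n matrix of co-assignment fractions in [0, 1],
#'   unit diagonal.
#' @slot nRepetitions Number of partitions aggregated.
#' @export
setClass("AgreementMatrix",
  representation(values = "matrix", nRepetitions = "integer")
)

setValidity("AgreementMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("entries must lie in [0,1]")
  if (max(abs(v - t(v))) > 1e-12) return("values not symmetric")
  if (any(abs(diag(v) - 1) > 1e-12)) return("diagonal must be 1")
  if (object@nRepetitions < 1L) return("nRepetitions must be >= 1")
  TRUE
})

# ---- accessors ----

#' @describeIn ConnectivityMatrix-class numeric matrix of z values
#' @param object A ConnectivityMatrix.
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connValues", "ConnectivityMatrix", function(object) object@values)

#' Node / ROI names of an object
#' @param object A ConnectivityMatrix or Partition.
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname roiNames
#' @export
setMethod("roiNames", "ConnectivityMatrix", function(object) object@roiNames)
#' @rdname roiNames
#' @export
setMethod("roiNames", "Partition", function(object) object@nodeNames)

#' Module labels of a partition
#' @param object A Partition.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "Partition", function(object) object@labels)

#' Number of modules in a partition
#' @param object A Partition.
#' @export
setGeneric("nModules", function(object) standardGeneric("nModules"))
#' @rdname nModules
#' @export
setMethod("nModules", "Partition", function(object) max(object@labels))

#' Quality-function value of a partition
#' @param object A Partition.
#' @export
setGeneric("modularityQ", function(object) standardGeneric("modularityQ"))
#' @rdname modularityQ
#' @export
setMethod("modularityQ", "Partition", function(object) object@modularityQ)

#' Agreement values and repetition count
#' @param object An AgreementMatrix.
#' @export
setGeneric("agreementValues", function(object) standardGeneric("agreementValues"))
#' @rdname agreementValues
#' @export
setMethod("agreementValues", "AgreementMatrix", function(object) object@values)

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf(
    "ConnectivityMatrix: %d x %d ROIs | subject %s | timepoint %s | %d session(s)\n",
    n, n, object@subjectId, object@timepointLabel, object@nSessionsAveraged))
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("  z range [%.3f, %.3f], mean %.3f\n",
              min(off), max(off), mean(off)))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition (%s): %d nodes, %d modules, gamma = %.2f, Q = %s\n",
              object@level, length(object@labels), max(object@labels),
              object@gamma,
              ifelse(is.na(object@modularityQ), "NA",
                     sprintf("%.4f", object@modularityQ))))
  cat("  module sizes:", paste(tabulate(object@labels), collapse = " "), "\n")
})

setMethod("show", "AgreementMatrix", function(object) {
  cat(sprintf("AgreementMatrix: %d nodes over %d repetitions\n",
              nrow(object@values), object@nRepetitions))
})
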