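#' @useDynLib netaging, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds through this one
#' function so that a single master seed determines every repetition, subject
#' and resolution sweep point. Uses a Lehmer-style mix kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the consumer (e.g. subject index,
#'   gamma index, repetition index).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

# internal: stop() with the offending field named, for spec-style validation
.check <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# canonical relabeling: module ids renumbered by first appearance
.canonicalLabels <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

# relabel modules by descending size, ties by lowest contained node index
.sortedLabels <- function(labels) {
  labels <- .canonicalLabels(labels)
  sz <- tabulate(labels)
  first <- vapply(seq_along(sz), function(k) min(which(labels == k)), 1L)
  ord <- order(-sz, first)
  match(labels, ord)
}

.upperTriPairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
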