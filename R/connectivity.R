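#' Pearson correlation matrix from ROI time series
#'
#' @param timeseries ROI x volumes numeric matrix (>= 3 volumes); rownames
#'   are taken as ROI names.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(timeseries) {
  .check(ncol(timeseries) >= 3, "timeseries: need at least 3 volumes")
  sds <- apply(timeseries, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(timeseries)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ROI: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(timeseries))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal. Correlations with
#' `|r| >= 1 - 1e-7` (e.g. duplicated series) are clipped to
#' `+/-(1 - 1e-7)` before the transform; the number of clipped edges is
#' recorded in the attribute `nClipped` and reported with a message when
#' positive. The diagonal is stored as 0.
#'
#' @param r Correlation matrix (`|r| <= 1` off-diagonal).
#' @param subjectId,timepointLabel Optional identifiers carried into the
#'   result.
#' @return A [ConnectivityMatrix-class].
#' @export
fisherZ <- function(r, subjectId = NA_character_,
                    timepointLabel = NA_character_) {
  lim <- 1 - 1e-7
  off <- r
  diag(off) <- 0
  nClipped <- sum(abs(off) >= lim)
  off[off > lim] <- lim
  off[off < -lim] <- -lim
  z <- atanh(off)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  if (nClipped > 0) {
    message(nClipped, " edge(s) clipped at |r| = 1 - 1e-7 before Fisher transform")
  }
  cm <- connectivityMatrix(z, roiNames = rownames(r), subjectId = subjectId,
                           timepointLabel = timepointLabel)
  attr(cm@values, "nClipped") <- NULL
  cm@values <- structure(cm@values, dimnames = dimnames(cm@values))
  attr(cm, "nClipped") <- nClipped
  cm
}

#' Average connectivity matrices across sessions
#'
#' Elementwise mean of the Fisher-z matrices of a subject's sessions at one
#' time point; `nSessionsAveraged` is set on the result.
#'
#' @param matrices List of [ConnectivityMatrix-class] with identical ROI
#'   ordering.
#' @return A [ConnectivityMatrix-class].
#' @export
averageSessions <- function(matrices) {
  .check(length(matrices) >= 1, "matrices: empty list")
  ref <- matrices[[1]]
  for (m in matrices) {
    if (!identical(m@roiNames, ref@roiNames)) {
      stop("mismatched ROI sets across sessions", call. = FALSE)
    }
  }
  if (length(matrices) == 1L) {
    ref@nSessionsAveraged <- 1L
    return(ref)
  }
  v <- Reduce(`+`, lapply(matrices, connValues)) / length(matrices)
  connectivityMatrix(v, roiNames = ref@roiNames, subjectId = ref@subjectId,
                     timepointLabel = ref@timepointLabel,
                     nSessionsAveraged = length(matrices))
}

#' Positive part of a connectivity matrix (Z+)
#'
#' Replaces negative z values by 0, leaving positive values unchanged.
#'
#' @param Z A [ConnectivityMatrix-class].
#' @return A [ConnectivityMatrix-class] with non-negative entries.
#' @export
positivePart <- function(Z) {
  v <- connValues(Z)
  v[v < 0] <- 0
  connectivityMatrix(v, roiNames = Z@roiNames, subjectId = Z@subjectId,
                     timepointLabel = Z@timepointLabel,
                     nSessionsAveraged = Z@nSessionsAveraged)
}

#' Group-level edge-wise one-sample tests
#'
#' For every unique (upper-triangle) edge: mean z across subjects, a
#' one-sample t statistic against zero, a one-sided upper-tail p-value,
#' Benjamini-Hochberg correction across the n(n-1)/2 unique edges, and a
#' significance mask at `alpha`. Edges with zero across-subject variance are
#' flagged degenerate (p = 0 if the mean is positive, 1 otherwise) with a
#' warning.
#'
#' @param Zs List of [ConnectivityMatrix-class] (>= 3 subjects, same ROI
#'   ordering).
#' @param alpha FDR level for the mask (default 0.05).
#' @return List: `mean` matrix, `t`, `p`, `neglog10p`, `q`, `mask` matrices,
#'   and a long data.frame `table` (roi_i, roi_j, mean_z, t, p, q).
#' @export
groupEdgeTest <- function(Zs, alpha = 0.05) {
  .check(length(Zs) >= 3, "Zs: need at least 3 subjects")
  ref <- Zs[[1]]
  n <- length(ref@roiNames)
  stack <- vapply(Zs, function(z) {
    .check(identical(z@roiNames, ref@roiNames), "mismatched ROI sets")
    connValues(z)[upper.tri(connValues(z))]
  }, numeric(n * (n - 1) / 2))
  m <- rowMeans(stack)
  s <- apply(stack, 1L, stats::sd)
  k <- length(Zs)
  tval <- m / (s / sqrt(k))
  degen <- s == 0
  if (any(degen)) {
    warning(sum(degen), " edge(s) with zero across-subject variance; ",
            "p recorded as degenerate")
    tval[degen] <- ifelse(m[degen] > 0, Inf, -Inf)
  }
  p <- stats::pt(tval, df = k - 1, lower.tail = FALSE)
  p[degen] <- ifelse(m[degen] > 0, 0, 1)
  q <- stats::p.adjust(p, method = "BH")

  toMat <- function(x, diagVal = 0) {
    mm <- matrix(diagVal, n, n, dimnames = list(ref@roiNames, ref@roiNames))
    mm[upper.tri(mm)] <- x
    mm[lower.tri(mm)] <- t(mm)[lower.tri(mm)]
    mm
  }
  pairs <- .upperTriPairs(n)
  list(mean = toMat(m), t = toMat(tval), p = toMat(p, diagVal = 1),
       neglog10p = toMat(-log10(pmax(p, 1e-300)), diagVal = 0),
       q = toMat(q, diagVal = 1), mask = toMat(q < alpha) > 0,
       table = data.frame(
         roi_i = ref@roiNames[pairs[, "row"]],
         roi_j = ref@roiNames[pairs[, "col"]],
         mean_z = m, t = tval, p = p, q = q,
         stringsAsFactors = FALSE))
}
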