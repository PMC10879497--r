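#' Network segregation index
#'
#' `SI = (mean within - mean between) / mean within`, where the means are
#' taken over strictly positive Fisher-z edges only (each unordered node pair
#' counted once). With `moduleSubset` the computation is restricted to the
#' subgraph of nodes in those modules: the within term uses same-module pairs
#' and the between term uses pairs spanning two different subset modules.
#' When no positive between edge exists the between mean is taken as 0 (so
#' SI = 1); when no positive within edge exists (or the within mean is not
#' positive) the SI is undefined and flagged.
#'
#' @param Z A [ConnectivityMatrix-class] (signed z; positive edges are
#'   selected internally) or a plain symmetric matrix.
#' @param part A [Partition-class] (or integer labels) covering Z's nodes.
#' @param moduleSubset Optional integer vector of module ids to restrict to.
#' @param negativePolicy `"exclude"` (default) drops non-positive edges from
#'   both means; `"zero"` keeps them in the denominator count as zeros.
#' @return A one-row data.frame: subject_id, timepoint_label, si,
#'   mean_within, mean_between, n_edges_within, n_edges_between,
#'   module_subset, defined.
#' @export
segregationIndex <- function(Z, part, moduleSubset = NULL,
                             negativePolicy = c("exclude", "zero")) {
  negativePolicy <- match.arg(negativePolicy)
  if (is(Z, "ConnectivityMatrix")) {
    v <- connValues(Z)
    sid <- Z@subjectId
    tp <- Z@timepointLabel
  } else {
    v <- Z
    sid <- NA_character_
    tp <- NA_character_
  }
  labels <- if (is(part, "Partition")) part@labels else as.integer(part)
  .check(length(labels) == nrow(v), "part: partition does not cover Z's nodes")
  n <- nrow(v)
  keep <- if (is.null(moduleSubset)) rep(TRUE, n) else labels %in% moduleSubset
  idx <- which(keep)
  ut <- upper.tri(v)
  same <- outer(labels, labels, `==`)
  inSub <- outer(keep, keep, `&`)
  wMask <- ut & inSub & same
  bMask <- ut & inSub & !same
  wVals <- v[wMask]
  bVals <- v[bMask]
  if (negativePolicy == "exclude") {
    wPos <- wVals[wVals > 0]
    bPos <- bVals[bVals > 0]
  } else {
    wPos <- pmax(wVals, 0)
    bPos <- pmax(bVals, 0)
  }
  meanW <- if (length(wPos)) mean(wPos) else NA_real_
  meanB <- if (length(bPos)) mean(bPos) else 0
  defined <- is.finite(meanW) && meanW > 0
  si <- if (defined) (meanW - meanB) / meanW else NA_real_
  data.frame(subject_id = sid, timepoint_label = tp, si = si,
             mean_within = meanW, mean_between = meanB,
             n_edges_within = length(wPos), n_edges_between = length(bPos),
             module_subset = if (is.null(moduleSubset)) "all" else
               paste(moduleSubset, collapse = "+"),
             defined = defined, stringsAsFactors = FALSE)
}

#' Segregation-index trajectories with a fixed baseline partition
#'
#' Computes the SI for every subject and time point using one fixed module
#' classification (typically the group consensus obtained at the first time
#' point), so that within/between edge sets are identical across ages, and
#' joins the result to the cohort design.
#'
#' @param matrices Named list of [ConnectivityMatrix-class] keyed
#'   `subject_timepoint` (as produced by [simulateCohortConnectivity()]).
#' @param baselinePartition [Partition-class] from the first time point.
#' @param cohort Cohort design data.frame (one row per session; deduplicated
#'   internally to subject x time point).
#' @param moduleSubset Optional module ids (e.g. the three most reliable).
#' @param negativePolicy See [segregationIndex()].
#' @return Long data.frame: one row per subject x time point with SI columns
#'   and the design columns (sex, cohort, group, age_days).
#' @export
siTrajectories <- function(matrices, baselinePartition, cohort,
                           moduleSubset = NULL,
                           negativePolicy = c("exclude", "zero")) {
  negativePolicy <- match.arg(negativePolicy)
  meta <- unique(cohort[, c("subject_id", "sex", "cohort", "group",
                            "timepoint_label", "age_days")])
  key <- paste(meta$subject_id, meta$timepoint_label, sep = "_")
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    Z <- matrices[[key[i]]]
    if (is.null(Z)) {
      message("no connectivity matrix for ", key[i], "; row omitted")
      next
    }
    r <- segregationIndex(Z, baselinePartition, moduleSubset, negativePolicy)
    r$subject_id <- meta$subject_id[i]
    r$timepoint_label <- meta$timepoint_label[i]
    rows[[length(rows) + 1L]] <- cbind(
      r, meta[i, c("sex", "cohort", "group", "age_days")])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag subjects with persistently low segregation
#'
#' A subject is flagged when its SI is below `threshold` (strict inequality:
#' a value exactly at the threshold is kept) at every one of the listed time
#' points that it was actually scanned at. Flagged subjects are meant to be
#' excluded from downstream statistics but are retained in the table.
#'
#' @param table Output of [siTrajectories()] (needs subject_id,
#'   timepoint_label, si).
#' @param threshold Exclusion threshold (default 0.43).
#' @param timepoints Time-point labels considered (default the two earliest
#'   present in the table).
#' @return The input table with a logical `excluded_flag` column.
#' @export
flagLowSi <- function(table, threshold = 0.43, timepoints = NULL) {
  if (is.null(timepoints)) {
    tps <- unique(table$timepoint_label)
    ord <- order(vapply(tps, function(t) {
      min(table$age_days[table$timepoint_label == t])
    }, 1.0))
    timepoints <- tps[ord][seq_len(min(2L, length(tps)))]
  }
  sub <- table[table$timepoint_label %in% timepoints & !is.na(table$si), ]
  flagged <- vapply(split(sub$si, sub$subject_id),
                    function(s) length(s) > 0 && all(s < threshold),
                    logical(1))
  flaggedIds <- names(flagged)[flagged]
  table$excluded_flag <- table$subject_id %in% flaggedIds
  table
}
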