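#' Write / read a connectivity matrix as square TSV
#'
#' The file has an ROI header row and a matching ROI first column. On read,
#' symmetry is required to 1e-8, ROI names must be unique, and the header row
#' must match the first column in order.
#'
#' @param Z A [ConnectivityMatrix-class] (or plain named square matrix).
#' @param path File path.
#' @return `writeMatrix`: the path, invisibly. `readMatrix`: a
#'   [ConnectivityMatrix-class].
#' @export
writeMatrix <- function(Z, path) {
  v <- if (is(Z, "ConnectivityMatrix")) connValues(Z) else Z
  df <- data.frame(roi = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "roi") {
    stop(path, ": first column must be 'roi'", call. = FALSE)
  }
  rois <- df$roi
  if (anyDuplicated(rois)) stop(path, ": duplicate ROI names", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), rois)) {
    stop(path, ": header ROI order does not match first column", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) stop(path, ": matrix not square", call. = FALSE)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(path, ": non-numeric or missing entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop(path, ": asymmetry beyond tolerance 1e-8", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- rois
  connectivityMatrix(m, roiNames = rois)
}

.cohortColumns <- c("subject_id", "sex", "cohort", "group",
                    "timepoint_label", "age_days", "session_id")

#' Write / read the cohort design table as CSV
#'
#' Strict schema: exactly the columns subject_id, sex, cohort, group,
#' timepoint_label, age_days, session_id.
#'
#' @param cohort Cohort design data.frame.
#' @param path File path.
#' @return `writeCohort`: the path, invisibly. `readCohort`: a data.frame.
#' @export
writeCohort <- function(cohort, path) {
  miss <- setdiff(.cohortColumns, names(cohort))
  .check(length(miss) == 0,
         paste0("cohort: missing column(s) ", paste(miss, collapse = ", ")))
  utils::write.csv(cohort[, .cohortColumns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohortColumns, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), .cohortColumns)
  if (length(extra)) {
    stop(path, ": unknown column(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$age_days)) stop(path, ": age_days must be numeric",
                                     call. = FALSE)
  df
}

#' Write a session's ROI time series as TSV
#'
#' Rows are ROIs (names in the first column), columns are volumes.
#'
#' @param ts ROI x volumes matrix with rownames.
#' @param path File path.
#' @export
writeSessionTimeseries <- function(ts, path) {
  df <- data.frame(roi = rownames(ts), ts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("roi", sprintf("v%04d", seq_len(ncol(ts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSessionTimeseries
#' @export
readSessionTimeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "roi") {
    stop(path, ": first column must be 'roi'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(path, ": non-numeric entries", call. = FALSE)
  rownames(m) <- df$roi
  m
}

#' Write a partition as two-column TSV (roi_name, module_id)
#'
#' @param part A [Partition-class].
#' @param path File path.
#' @export
writePartition <- function(part, path) {
  nm <- part@nodeNames
  if (!length(nm)) nm <- sprintf("node_%02d", seq_along(part@labels))
  utils::write.table(
    data.frame(roi_name = nm, module_id = part@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @param gamma,level Metadata for the reconstructed partition.
#' @export
readPartition <- function(path, gamma = NA_real_, level = "group-consensus") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  partition(df$module_id, gamma = gamma, level = level,
            nodeNames = df$roi_name)
}
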