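#' Fit a linear mixed-effects aging trajectory
#'
#' Fits `outcome ~ 1 + age * factor + (1 | subject)` by maximum likelihood
#' (lme4). Age enters in exact days, centered at the grand mean and rescaled
#' to months (days / 30.44) internally for conditioning; slope estimates are
#' reported both per month (the fitted scale) and per day. The factor is
#' treatment-coded with female (for `sex`) or group X (for `group`) as the
#' reference level. Wald t statistics use residual degrees of freedom
#' (observations minus fixed effects).
#'
#' @param data Long data.frame with columns `subject_id`, `age_days`, the
#'   outcome column, and (unless `factor = "none"`) the factor column
#'   (`sex`: F/M, or `group`: X/Y).
#' @param outcome Name of the outcome column.
#' @param factor One of "none", "sex", "group".
#' @return An object of class `LMEResult`: list with `coefficients`
#'   (data.frame: term, estimate, se, t, p, estimate_per_day), `df`,
#'   `nSubjects`, `nObservations`, `converged`, `singular`, `vcov`,
#'   `ageScale` (days per fitted age unit), `factor`, `outcome`, `fit`.
#' @export
fitLME <- function(data, outcome = "si", factor = c("none", "sex", "group")) {
  factor <- match.arg(factor)
  need <- c("subject_id", "age_days", outcome,
            if (factor != "none") factor)
  miss <- setdiff(need, names(data))
  .check(length(miss) == 0,
         paste0("data: missing column(s) ", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  .check(length(unique(d$subject_id)) >= 2, "data: need >= 2 subjects")
  .check(nrow(d) >= 4, "data: need >= 4 observations")

  daysPerMonth <- 30.44
  d$.age <- (d$age_days - mean(d$age_days)) / daysPerMonth
  d$.y <- d[[outcome]]
  if (factor == "sex") {
    d$.f <- stats::relevel(base::factor(d$sex), ref = "F")
  } else if (factor == "group") {
    d$.f <- stats::relevel(base::factor(d$group), ref = "X")
  }
  form <- if (factor == "none") {
    .y ~ 1 + .age + (1 | subject_id)
  } else {
    .y ~ 1 + .age * .f + (1 | subject_id)
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, converged = FALSE,
                          singular = NA, message = conditionMessage(fit),
                          factor = factor, outcome = outcome),
                     class = "LMEResult"))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  nObs <- nrow(d)
  df <- nObs - nrow(co)
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  terms <- rownames(co)
  ageTerms <- grepl("^\\.age", terms)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(
    coefficients = data.frame(
      term = gsub("\\.f", if (factor == "none") "" else factor, terms),
      estimate = unname(est), se = unname(se), t = unname(tval),
      p = unname(pval),
      estimate_per_day = unname(ifelse(ageTerms, est / daysPerMonth, est)),
      stringsAsFactors = FALSE),
    df = df, nSubjects = length(unique(d$subject_id)),
    nObservations = nObs, converged = conv,
    singular = lme4::isSingular(fit), vcov = as.matrix(stats::vcov(fit)),
    ageScale = daysPerMonth, factor = factor, outcome = outcome,
    fit = fit), class = "LMEResult")
}

#' @export
print.LMEResult <- function(x, ...) {
  cat(sprintf("LME (ML): %s ~ age %s + (1 | subject)\n", x$outcome,
              if (x$factor == "none") "" else paste("*", x$factor)))
  if (is.null(x$coefficients)) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %d subjects, %d observations, df = %d%s%s\n",
              x$nSubjects, x$nObservations, x$df,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (isTRUE(x$singular)) " [singular]" else ""))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Time (age) effect as an equal-weight contrast over factor levels
#'
#' For a two-level factor model, the age effect averaged with weight 1/2 per
#' level: `age + 0.5 * age:factor` under treatment coding. The variance is
#' `c' Sigma c` from the coefficient covariance.
#'
#' @param result An `LMEResult` fitted with a factor (interaction present).
#' @return List: estimate (per fitted age unit), estimate_per_day, se, t, p,
#'   df.
#' @export
timeContrast <- function(result) {
  .check(inherits(result, "LMEResult") && !is.null(result$coefficients),
         "result: need a successful LMEResult")
  terms <- rownames(result$vcov)
  ageIdx <- which(terms == ".age")
  intIdx <- grep("^\\.age:", terms)
  if (length(ageIdx) != 1 || length(intIdx) != 1) {
    stop("missing interaction term: fit with factor = 'sex' or 'group'",
         call. = FALSE)
  }
  cvec <- numeric(length(terms))
  cvec[ageIdx] <- 1
  cvec[intIdx] <- 0.5
  # coefficients table rows are in vcov order
  est <- sum(cvec * result$coefficients$estimate)
  se <- sqrt(drop(t(cvec) %*% result$vcov %*% cvec))
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df = result$df, lower.tail = FALSE)
  list(estimate = est, estimate_per_day = est / result$ageScale, se = se,
       t = tval, p = p, df = result$df)
}

#' Mass-univariate LME over edges, nodes or regions
#'
#' Fits [fitLME()] per unit (e.g. per edge or per bilateral region), extracts
#' the age effect — the age coefficient for `factor = "none"`, otherwise the
#' equal-weight [timeContrast()] — and applies Benjamini-Hochberg correction
#' across the units that converged. Units whose fit fails are excluded from
#' the FDR family and counted.
#'
#' @param table Long data.frame with columns `unit`, `value`, `subject_id`,
#'   `age_days`, and the factor column if used.
#' @param factor Passed to [fitLME()].
#' @param alpha FDR level for the corrected mask (default 0.05).
#' @param pUncorrected Display threshold for the uncorrected mask
#'   (default 0.01).
#' @return data.frame: unit, slope_per_day, t, p, q, sign, sig_fdr,
#'   sig_uncorrected; attribute `nFailed`.
#' @export
massUnivariateLME <- function(table, factor = c("none", "sex", "group"),
                              alpha = 0.05, pUncorrected = 0.01) {
  factor <- match.arg(factor)
  units <- split(table, table$unit)
  rows <- lapply(names(units), function(u) {
    res <- tryCatch(fitLME(units[[u]], outcome = "value", factor = factor),
                    error = function(e) NULL)
    if (is.null(res) || is.null(res$coefficients)) return(NULL)
    eff <- if (factor == "none") {
      i <- which(res$coefficients$term == ".age")
      list(estimate_per_day = res$coefficients$estimate_per_day[i],
           t = res$coefficients$t[i], p = res$coefficients$p[i])
    } else {
      timeContrast(res)
    }
    data.frame(unit = u, slope_per_day = eff$estimate_per_day, t = eff$t,
               p = eff$p, stringsAsFactors = FALSE)
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows)
  .check(!is.null(out), "table: no unit could be fitted")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$sign <- sign(out$slope_per_day)
  out$sig_fdr <- out$q < alpha
  out$sig_uncorrected <- out$p < pUncorrected
  rownames(out) <- NULL
  attr(out, "nFailed") <- failed
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of slope distributions
#'
#' Statistic is the supremum ECDF difference; the p-value is asymptotic.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List: statistic, p.
#' @export
ksCompare <- function(a, b) {
  .check(length(a) >= 1 && length(b) >= 1, "a/b: both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Segregation-index trajectory analysis across strata
#'
#' Fits the SI trajectory (age slope, ML mixed model with subject intercepts)
#' overall and within each sex, cohort and group stratum, after removing
#' subjects flagged by [flagLowSi()] (if the `excluded_flag` column is
#' present). Strata with fewer than 3 subjects are skipped with a warning.
#'
#' @param siTable Output of [siTrajectories()] (optionally flagged).
#' @return data.frame: stratum, level, slope_per_day, se_per_day, t, p, df,
#'   n_subjects, n_observations.
#' @export
siTrajectoryAnalysis <- function(siTable) {
  if ("excluded_flag" %in% names(siTable)) {
    siTable <- siTable[!siTable$excluded_flag, ]
  }
  siTable <- siTable[!is.na(siTable$si), ]
  strata <- list(list("overall", "all", siTable))
  for (col in c("sex", "cohort", "group")) {
    if (!col %in% names(siTable)) next
    for (lev in sort(unique(siTable[[col]]))) {
      strata[[length(strata) + 1L]] <-
        list(col, lev, siTable[siTable[[col]] == lev, ])
    }
  }
  rows <- lapply(strata, function(s) {
    d <- s[[3]]
    if (length(unique(d$subject_id)) < 3) {
      warning(sprintf("stratum %s=%s skipped: fewer than 3 subjects",
                      s[[1]], s[[2]]))
      return(NULL)
    }
    res <- fitLME(d, outcome = "si", factor = "none")
    if (is.null(res$coefficients)) return(NULL)
    i <- which(res$coefficients$term == ".age")
    data.frame(stratum = s[[1]], level = s[[2]],
               slope_per_day = res$coefficients$estimate_per_day[i],
               se_per_day = res$coefficients$se[i] / res$ageScale,
               t = res$coefficients$t[i], p = res$coefficients$p[i],
               df = res$df,
               n_subjects = res$nSubjects, n_observations = res$nObservations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
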