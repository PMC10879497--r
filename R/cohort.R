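#' CohortSpec: design of a synthetic longitudinal imaging cohort
#'
#' Describes the study design the generator emulates: several cohorts of both
#' sexes scanned at three target ages (about 12, 18 and 24 months, expressed
#' in days), one or two sessions per time point, with subject dropout between
#' time points and group-dependent linear aging of within- and between-module
#' correlations around a planted bilateral modular structure.
#'
#' @slot nSubjectsPerCell Subjects per (sex, cohort) cell.
#' @slot cohorts Named character vector mapping cohort label to group
#'   ("X" or "Y").
#' @slot timepointsDays Target ages in days, strictly increasing.
#' @slot sessionsPerTimepoint Sessions acquired per time point.
#' @slot nVolumes Usable volumes per session.
#' @slot nRois Number of ROIs (even; ROIs come in left/right pairs).
#' @slot plantedPartition Module label per ROI, mirror-symmetric across
#'   hemispheres.
#' @slot withinR0,betweenR0 Baseline Pearson correlations at the first time
#'   point.
#' @slot withinSlope,betweenSlope Named numeric (per group) change in
#'   correlation per day.
#' @slot subjectSd SD of the per-subject random offset added to both
#'   correlations.
#' @slot dropoutProb Probability a surviving subject is lost before each
#'   later time point.
#' @slot arCoef Optional AR(1) coefficient for the simulated time series
#'   (default 0, i.e. volumes i.i.d.).
#' @slot ageJitterDays Half-width of the uniform jitter on exact ages.
#' @slot seed Default seed for generation.
#' @export
setClass("CohortSpec",
  representation(
    nSubjectsPerCell = "integer",
    cohorts = "character",
    timepointsDays = "numeric",
    sessionsPerTimepoint = "integer",
    nVolumes = "integer",
    nRois = "integer",
    plantedPartition = "integer",
    withinR0 = "numeric",
    betweenR0 = "numeric",
    withinSlope = "numeric",
    betweenSlope = "numeric",
    subjectSd = "numeric",
    dropoutProb = "numeric",
    arCoef = "numeric",
    ageJitterDays = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@nSubjectsPerCell < 1L) return("nSubjectsPerCell must be >= 1")
  if (length(object@cohorts) < 1L || is.null(names(object@cohorts))) {
    return("cohorts must be a named vector (cohort -> group)")
  }
  if (!all(object@cohorts %in% c("X", "Y"))) {
    return("cohorts: group assignment must be 'X' or 'Y'")
  }
  if (any(diff(object@timepointsDays) <= 0)) {
    return("timepointsDays must be strictly increasing")
  }
  if (object@nRois %% 2L != 0L) return("nRois must be even (L/R pairs)")
  p <- object@plantedPartition
  if (length(p) != object@nRois) {
    return("plantedPartition length must equal nRois")
  }
  odd <- p[seq(1L, object@nRois, by = 2L)]
  even <- p[seq(2L, object@nRois, by = 2L)]
  if (!all(odd == even)) {
    return("plantedPartition must be mirror-symmetric (L/R pairs share labels)")
  }
  if (!(object@betweenR0 >= 0 && object@betweenR0 < object@withinR0 &&
        object@withinR0 < 1)) {
    return("need 0 <= betweenR0 < withinR0 < 1")
  }
  if (object@dropoutProb < 0 || object@dropoutProb >= 1) {
    return("dropoutProb must lie in [0, 1)")
  }
  grps <- unique(unname(object@cohorts))
  if (!all(grps %in% names(object@withinSlope)) ||
      !all(grps %in% names(object@betweenSlope))) {
    return("withinSlope/betweenSlope must be named for every group used")
  }
  if (abs(object@arCoef) >= 1) return("arCoef must satisfy |arCoef| < 1")
  if (object@nVolumes < 10L) return("nVolumes must be >= 10")
  TRUE
})

#' Construct a CohortSpec
#'
#' Defaults emulate the study design this package targets: 72 bilateral ROIs
#' in 6 planted modules of 12, scans at 365/548/730 days with two sessions of
#' 415 usable volumes each, two cohorts (one per group) of both sexes, 12%
#' dropout before each later time point, and group X showing de-segregation
#' with age (within-module correlation falling, between-module rising) while
#' group Y stays flat. The default slopes make the planted three-module
#' segregation index decline by roughly 0.1 between 12 and 24 months.
#'
#' @param nSubjectsPerCell Subjects per (sex, cohort) cell (default 4).
#' @param cohorts Named character vector cohort -> group (default
#'   `c(A = "Y", B = "X")`).
#' @param timepointsDays Target ages in days (default 365, 548, 730).
#' @param sessionsPerTimepoint Default 2.
#' @param nVolumes Default 415.
#' @param nRois Default 72 (even).
#' @param plantedPartition Module label per ROI; default 6 equal modules with
#'   consecutive L/R pairs sharing a label.
#' @param withinR0,betweenR0 Baseline correlations (defaults 0.5, 0.1).
#' @param withinSlope,betweenSlope Per-group slopes in correlation units per
#'   day (defaults: X declines within at -1.5e-4/day and gains between at
#'   +1e-4/day; Y flat).
#' @param subjectSd SD of subject offsets (default 0.02).
#' @param dropoutProb Per-interval dropout probability (default 0.12).
#' @param arCoef AR(1) coefficient for time series (default 0).
#' @param ageJitterDays Age jitter half-width (default 14).
#' @param seed Default generation seed.
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjectsPerCell = 4L,
                       cohorts = c(A = "Y", B = "X"),
                       timepointsDays = c(365, 548, 730),
                       sessionsPerTimepoint = 2L,
                       nVolumes = 415L,
                       nRois = 72L,
                       plantedPartition = NULL,
                       withinR0 = 0.5,
                       betweenR0 = 0.1,
                       withinSlope = c(X = -1.5e-4, Y = 0),
                       betweenSlope = c(X = 1e-4, Y = 0),
                       subjectSd = 0.02,
                       dropoutProb = 0.12,
                       arCoef = 0,
                       ageJitterDays = 14,
                       seed = 1L) {
  nRois <- as.integer(nRois)
  if (is.null(plantedPartition)) {
    nMod <- 6L
    .check(nRois %% (2L * nMod) == 0L,
           "nRois: default planted partition needs nRois divisible by 12")
    plantedPartition <- rep(seq_len(nMod), each = nRois / nMod)
  }
  new("CohortSpec",
      nSubjectsPerCell = as.integer(nSubjectsPerCell),
      cohorts = cohorts,
      timepointsDays = as.numeric(timepointsDays),
      sessionsPerTimepoint = as.integer(sessionsPerTimepoint),
      nVolumes = as.integer(nVolumes),
      nRois = nRois,
      plantedPartition = as.integer(plantedPartition),
      withinR0 = withinR0, betweenR0 = betweenR0,
      withinSlope = withinSlope, betweenSlope = betweenSlope,
      subjectSd = subjectSd, dropoutProb = dropoutProb,
      arCoef = arCoef, ageJitterDays = ageJitterDays,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  nsub <- object@nSubjectsPerCell * 2L * length(object@cohorts)
  cat(sprintf(
    "CohortSpec: %d subjects (%d per sex x cohort cell), cohorts [%s]\n",
    nsub, object@nSubjectsPerCell,
    paste(sprintf("%s=%s", names(object@cohorts), object@cohorts),
          collapse = ", ")))
  cat(sprintf("  %d ROIs, %d planted modules; timepoints (days): %s\n",
              object@nRois, max(object@plantedPartition),
              paste(object@timepointsDays, collapse = ", ")))
  cat(sprintf("  r0 within/between %.2f/%.2f, dropout %.2f, subject sd %.3f\n",
              object@withinR0, object@betweenR0, object@dropoutProb,
              object@subjectSd))
})

# default ROI names: region pairs r01_L, r01_R, r02_L, ...
.defaultRoiNames <- function(nRois) {
  region <- rep(seq_len(nRois / 2L), each = 2L)
  side <- rep(c("L", "R"), nRois / 2L)
  sprintf("r%02d_%s", region, side)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Within/between correlation targets for a subject at a given age
#'
#' Linear-in-days aging on the correlation scale, with the subject's random
#' offset added to both the within- and between-module targets, clipped to
#' `[0, 0.95]`. Slopes are taken from the subject's group, so group X (by
#' default) de-segregates with age while group Y stays flat.
#'
#' @param spec A [CohortSpec-class].
#' @param group Group label ("X" or "Y").
#' @param ageDays Exact age in days.
#' @param offset Per-subject random offset (default 0).
#' @return Named numeric `c(within, between)`.
#' @export
agingEffect <- function(spec, group, ageDays, offset = 0) {
  dt <- ageDays - spec@timepointsDays[1]
  w <- spec@withinR0 + spec@withinSlope[[group]] * dt + offset
  b <- spec@betweenR0 + spec@betweenSlope[[group]] * dt + offset
  c(within = min(max(w, 0), 0.95), between = min(max(b, 0), 0.95))
}

# segregation index of a noiseless equal-valued block target, on the z scale,
# under the positive-edges-only convention
.blockSi <- function(withinR, betweenR) {
  zw <- atanh(withinR)
  zb <- atanh(betweenR)
  if (zw <= 0) return(NA_real_)
  if (zb <= 0) zb <- 0
  (zw - zb) / zw
}

#' Build the longitudinal design table and ground truth for a cohort
#'
#' Enumerates subjects over (sex, cohort) cells, applies cumulative dropout
#' before each later time point, jitters exact ages around the targets, and
#' precomputes each subject's true correlation targets and segregation-index
#' trajectory. Fully deterministic given `seed`.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer seed (defaults to `spec@seed`).
#' @return A list with elements `design` (data.frame: one row per surviving
#'   subject x time point x session) and `groundTruth` (planted partition,
#'   subject offsets, per subject/time point true within/between r and true
#'   segregation index).
#' @export
buildCohortDesign <- function(spec, seed = spec@seed) {
  validObject(spec)
  .withSeed(deriveSeed(seed, 1L), {
    cells <- expand.grid(sex = c("F", "M"), cohort = names(spec@cohorts),
                         stringsAsFactors = FALSE)
    subj <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(sex = cells$sex[i], cohort = cells$cohort[i],
                 idx = seq_len(spec@nSubjectsPerCell),
                 stringsAsFactors = FALSE)
    }))
    subj$subject_id <- sprintf("s%03d", seq_len(nrow(subj)))
    subj$group <- unname(spec@cohorts[subj$cohort])
    subj$offset <- stats::rnorm(nrow(subj), 0, spec@subjectSd)

    nTp <- length(spec@timepointsDays)
    tpLabels <- sprintf("%.0fmo", round(spec@timepointsDays / 30.44))
    # cumulative survival: drop before each later time point
    present <- matrix(TRUE, nrow(subj), nTp)
    for (t in seq.int(2L, length.out = nTp - 1L)) {
      drop <- stats::runif(nrow(subj)) < spec@dropoutProb
      present[, t] <- present[, t - 1L] & !drop
    }
    # exact ages: one jitter per subject x timepoint (shared across sessions)
    jitter <- matrix(
      stats::runif(nrow(subj) * nTp, -spec@ageJitterDays, spec@ageJitterDays),
      nrow(subj), nTp)
    ages <- sweep(round(jitter), 2L, round(spec@timepointsDays), `+`)

    rows <- list()
    truthRows <- list()
    for (s in seq_len(nrow(subj))) {
      for (t in seq_len(nTp)) {
        if (!present[s, t]) next
        age <- ages[s, t]
        tr <- agingEffect(spec, subj$group[s], age, subj$offset[s])
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          subject_id = subj$subject_id[s], timepoint_label = tpLabels[t],
          age_days = age, within_r = unname(tr["within"]),
          between_r = unname(tr["between"]),
          si = .blockSi(tr["within"], tr["between"]),
          stringsAsFactors = FALSE)
        for (sess in seq_len(spec@sessionsPerTimepoint)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subj$subject_id[s], sex = subj$sex[s],
            cohort = subj$cohort[s], group = subj$group[s],
            timepoint_label = tpLabels[t], age_days = age,
            session_id = sprintf("%s_%s_ses%d", subj$subject_id[s],
                                 tpLabels[t], sess),
            stringsAsFactors = FALSE)
        }
      }
    }
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    list(design = design,
         groundTruth = list(
           plantedPartition = spec@plantedPartition,
           roiNames = .defaultRoiNames(spec@nRois),
           subjects = subj[, c("subject_id", "sex", "cohort", "group",
                               "offset")],
           trajectories = truth))
  })
}

#' Block-structured target correlation matrix for a planted partition
#'
#' Unit diagonal; `withinR` for same-module pairs, `betweenR` otherwise. If
#' the result is not positive definite it is repaired by flooring eigenvalues
#' at 1e-6 and renormalizing to unit diagonal, and the attribute `repaired`
#' is set to `TRUE`.
#'
#' @param labels Integer module label per ROI.
#' @param withinR,betweenR Correlations with `0 <= betweenR <= withinR < 1`.
#' @return Correlation matrix with attribute `repaired` (logical).
#' @export
targetCorrelationMatrix <- function(labels, withinR, betweenR) {
  .check(withinR < 1, "withinR: must be < 1")
  .check(betweenR >= 0 && betweenR <= withinR,
         "betweenR: need 0 <= betweenR <= withinR")
  same <- outer(labels, labels, `==`)
  m <- ifelse(same, withinR, betweenR)
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) <= 0) {
    e <- eigen(m, symmetric = TRUE)
    vals <- pmax(e$values, 1e-6)
    m <- e$vectors %*% diag(vals) %*% t(e$vectors)
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
    repaired <- TRUE
  }
  attr(m, "repaired") <- repaired
  m
}

#' Simulate a session of ROI time series with a given population correlation
#'
#' Draws zero-mean Gaussian volumes whose population correlation equals the
#' target matrix. With `arCoef != 0` each latent series is AR(1) with that
#' coefficient (stationary, unit marginal variance), which leaves the
#' cross-ROI population correlation unchanged.
#'
#' @param target Positive-definite correlation matrix (ROI x ROI).
#' @param nVolumes Number of volumes (>= 10).
#' @param seed Integer seed.
#' @param arCoef AR(1) coefficient, `|arCoef| < 1` (default 0).
#' @return ROI x volumes numeric matrix.
#' @export
simulateTimeseries <- function(target, nVolumes, seed, arCoef = 0) {
  .check(nVolumes >= 10, "nVolumes: must be >= 10")
  R <- tryCatch(chol(target),
                error = function(e) stop("target matrix is not positive definite",
                                         call. = FALSE))
  n <- nrow(target)
  .withSeed(seed, {
    z <- matrix(stats::rnorm(nVolumes * n), nVolumes, n)
    if (arCoef != 0) {
      z <- apply(z, 2L, function(x) {
        y <- stats::filter(x, arCoef, method = "recursive")
        as.numeric(y) * sqrt(1 - arCoef^2)
      })
    }
    t(z %*% R)   # ROI x volumes
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [buildCohortDesign()] and then simulates every session's ROI time
#' series from the subject's true target correlation matrix at that age.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer seed (defaults to `spec@seed`).
#' @return List: `design`, `groundTruth`, and `sessions` — a named list of
#'   ROI x volumes matrices, one per design row (named by `session_id`).
#' @export
simulateCohort <- function(spec, seed = spec@seed) {
  dg <- buildCohortDesign(spec, seed)
  design <- dg$design
  truth <- dg$groundTruth$trajectories
  roiNames <- dg$groundTruth$roiNames
  key <- paste(design$subject_id, design$timepoint_label)
  tkey <- paste(truth$subject_id, truth$timepoint_label)
  sessions <- vector("list", nrow(design))
  names(sessions) <- design$session_id
  for (i in seq_len(nrow(design))) {
    tr <- truth[match(key[i], tkey), ]
    target <- targetCorrelationMatrix(spec@plantedPartition,
                                      tr$within_r, tr$between_r)
    ts <- simulateTimeseries(target, spec@nVolumes,
                             deriveSeed(seed, 2L, i), spec@arCoef)
    rownames(ts) <- roiNames
    sessions[[i]] <- ts
  }
  list(design = design, groundTruth = dg$groundTruth, sessions = sessions)
}

#' Simulate a cohort and reduce it to subject-level connectivity matrices
#'
#' Convenience wrapper: simulate sessions, compute Pearson correlations and
#' Fisher z per session, and average sessions within subject x time point.
#'
#' @inheritParams simulateCohort
#' @return List: `design`, `groundTruth`, and `matrices` — a named list of
#'   [ConnectivityMatrix-class] objects keyed `subject_timepoint`.
#' @export
simulateCohortConnectivity <- function(spec, seed = spec@seed) {
  sim <- simulateCohort(spec, seed)
  design <- sim$design
  key <- paste(design$subject_id, design$timepoint_label, sep = "_")
  mats <- lapply(split(seq_len(nrow(design)), key), function(idx) {
    zs <- lapply(idx, function(i) {
      fisherZ(pearsonMatrix(sim$sessions[[i]]),
              subjectId = design$subject_id[i],
              timepointLabel = design$timepoint_label[i])
    })
    averageSessions(zs)
  })
  list(design = design, groundTruth = sim$groundTruth, matrices = mats)
}
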