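#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run. Round-trips losslessly through
#' YAML ([writeRunConfig()] / [readRunConfig()]); [configHash()] changes iff
#' any field changes.
#'
#' @param mode "simulate" (default), "timeseries" or "matrices".
#' @param inputDir Directory of input TSVs for the non-simulate modes.
#' @param cohortFile Cohort CSV for the non-simulate modes.
#' @param spec A [CohortSpec-class] for simulate mode (default
#'   `cohortSpec()`).
#' @param gammas Resolution grid (default `seq(1, 2, by = 0.1)`).
#' @param nReps Louvain repetitions per subject (default 100; the reference
#'   analysis scale is 1000).
#' @param densities Density grid (default [defaultDensities()]).
#' @param siThreshold Low-SI exclusion threshold (default 0.43).
#' @param fdrAlpha FDR level (default 0.05).
#' @param nReliableModules Size of the reliable-module subset (default 3).
#' @param seed Master seed (mandatory).
#' @param outDir Output directory.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("simulate", "timeseries", "matrices"),
                      inputDir = NULL, cohortFile = NULL,
                      spec = cohortSpec(),
                      gammas = seq(1, 2, by = 0.1), nReps = 100L,
                      densities = defaultDensities(),
                      siThreshold = 0.43, fdrAlpha = 0.05,
                      nReliableModules = 3L,
                      seed = NULL, outDir = tempfile("netaging_run_")) {
  mode <- match.arg(mode)
  .check(!is.null(seed), "seed: mandatory")
  .check(all(diff(gammas) > 0) && all(gammas > 0), "gammas: invalid grid")
  .check(all(diff(densities) > 0) && all(densities > 0) &&
           all(densities <= 1), "densities: invalid grid")
  .check(nReps >= 1, "nReps: must be >= 1")
  if (mode != "simulate") {
    .check(!is.null(inputDir) && !is.null(cohortFile),
           "inputDir/cohortFile: required unless mode = 'simulate'")
  }
  structure(list(mode = mode, inputDir = inputDir, cohortFile = cohortFile,
                 spec = spec, gammas = gammas, nReps = as.integer(nReps),
                 densities = densities, siThreshold = siThreshold,
                 fdrAlpha = fdrAlpha,
                 nReliableModules = as.integer(nReliableModules),
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.specToList <- function(spec) {
  sl <- attributes(spec)
  sl$class <- NULL
  # named vectors become maps so YAML keeps the names
  sl <- lapply(sl, function(x) if (!is.null(names(x))) as.list(x) else x)
  sl[sort(names(sl))]
}

#' Hash of a run configuration
#'
#' @param config A `RunConfig`.
#' @return Character hash; identical iff every field (except `outDir`) is
#'   identical.
#' @export
configHash <- function(config) {
  x <- unclass(config)
  x$outDir <- NULL
  if (is(x$spec, "CohortSpec")) x$spec <- .specToList(x$spec)
  rlang::hash(x)
}

#' @rdname runConfig
#' @param config A `RunConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  if (is(x$spec, "CohortSpec")) x$spec <- .specToList(x$spec)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- x$spec
  if (!is.null(spec)) {
    spec <- new("CohortSpec",
                nSubjectsPerCell = as.integer(spec$nSubjectsPerCell),
                cohorts = unlist(spec$cohorts),
                timepointsDays = as.numeric(spec$timepointsDays),
                sessionsPerTimepoint = as.integer(spec$sessionsPerTimepoint),
                nVolumes = as.integer(spec$nVolumes),
                nRois = as.integer(spec$nRois),
                plantedPartition = as.integer(spec$plantedPartition),
                withinR0 = spec$withinR0, betweenR0 = spec$betweenR0,
                withinSlope = unlist(spec$withinSlope),
                betweenSlope = unlist(spec$betweenSlope),
                subjectSd = spec$subjectSd, dropoutProb = spec$dropoutProb,
                arCoef = spec$arCoef, ageJitterDays = spec$ageJitterDays,
                seed = as.integer(spec$seed))
  }
  runConfig(mode = x$mode, inputDir = x$inputDir, cohortFile = x$cohortFile,
            spec = spec, gammas = as.numeric(x$gammas),
            nReps = as.integer(x$nReps),
            densities = as.numeric(x$densities),
            siThreshold = x$siThreshold, fdrAlpha = x$fdrAlpha,
            nReliableModules = as.integer(x$nReliableModules),
            seed = as.integer(x$seed), outDir = x$outDir)
}

.loadMatrices <- function(config) {
  cohort <- readCohort(config$cohortFile)
  key <- unique(paste(cohort$subject_id, cohort$timepoint_label, sep = "_"))
  mats <- lapply(key, function(k) {
    p <- file.path(config$inputDir, paste0(k, ".tsv"))
    if (!file.exists(p)) stop("missing matrix file: ", p, call. = FALSE)
    z <- readMatrix(p)
    parts <- strsplit(k, "_")[[1]]
    z@subjectId <- parts[1]
    z@timepointLabel <- parts[2]
    z
  })
  names(mats) <- key
  list(design = cohort, matrices = mats, groundTruth = NULL)
}

.loadTimeseries <- function(config) {
  cohort <- readCohort(config$cohortFile)
  key <- paste(cohort$subject_id, cohort$timepoint_label, sep = "_")
  mats <- lapply(split(seq_len(nrow(cohort)), key), function(idx) {
    zs <- lapply(idx, function(i) {
      p <- file.path(config$inputDir, paste0(cohort$session_id[i], ".tsv"))
      if (!file.exists(p)) stop("missing session file: ", p, call. = FALSE)
      fisherZ(pearsonMatrix(readSessionTimeseries(p)),
              subjectId = cohort$subject_id[i],
              timepointLabel = cohort$timepoint_label[i])
    })
    averageSessions(zs)
  })
  list(design = cohort, matrices = mats, groundTruth = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: simulate (or load) -> connectivity -> consensus modules with
#' resolution sweep (on the first-time-point matrices) -> segregation index
#' (all modules and the reliable-module subset, with low-SI flagging) ->
#' density-thresholded graph metrics -> mixed-model trajectory statistics.
#' All artifacts are written under `config$outDir` together with a manifest
#' (seed, config hash, per-stage row counts). The run is a pure function of
#' (config, seed).
#'
#' @param config A `RunConfig`.
#' @param verbose Print stage progress (default TRUE).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  .check(inherits(config, "RunConfig"), "config: must be a RunConfig")
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "matrices"), showWarnings = FALSE)
  say <- function(...) if (verbose) message("[netaging] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(package = "netaging",
                   version = as.character(utils::packageVersion("netaging")),
                   seed = config$seed, config_hash = configHash(config),
                   counts = list())

  dat <- stage("input", {
    switch(config$mode,
      simulate = simulateCohortConnectivity(config$spec, config$seed),
      matrices = .loadMatrices(config),
      timeseries = .loadTimeseries(config))
  })
  design <- dat$design
  mats <- dat$matrices
  writeCohort(design, file.path(out, "cohort.csv"))
  if (!is.null(dat$groundTruth)) {
    jsonlite::write_json(dat$groundTruth,
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest$counts$cohort_rows <- nrow(design)
  manifest$counts$subject_timepoints <- length(mats)

  stage("connectivity", {
    for (k in names(mats)) {
      writeMatrix(mats[[k]], file.path(out, "matrices", paste0(k, ".tsv")))
    }
  })

  tps <- unique(design$timepoint_label[order(design$age_days)])
  baseTp <- tps[1]
  matsByTp <- lapply(tps, function(tp) {
    mats[vapply(mats, function(m) m@timepointLabel == tp, logical(1))]
  })
  names(matsByTp) <- tps

  modules <- stage("modules", {
    sweep <- gammaSweep(matsByTp[[baseTp]], gammas = config$gammas,
                        nReps = config$nReps, seed = deriveSeed(config$seed, 21L))
    # per-time-point group partitions at the selected gamma, for module flow
    tpParts <- lapply(seq_along(tps), function(ti) {
      if (tps[ti] == baseTp) return(sweep$selectedPartition)
      sp <- lapply(seq_along(matsByTp[[ti]]), function(s) {
        subjectConsensus(connValues(positivePart(matsByTp[[ti]][[s]])),
                         gamma = sweep$selectedGamma, nReps = config$nReps,
                         seed = deriveSeed(config$seed, 22L, ti, s))$partition
      })
      groupConsensus(sp, gamma = sweep$selectedGamma,
                     seed = deriveSeed(config$seed, 23L, ti))
    })
    names(tpParts) <- tps
    # classification consistency of baseline single runs vs group consensus
    baseReps <- unlist(lapply(seq_along(matsByTp[[baseTp]]), function(s) {
      repeatedPartitions(connValues(positivePart(matsByTp[[baseTp]][[s]])),
                         gamma = sweep$selectedGamma,
                         nReps = max(1L, config$nReps %/% 10L),
                         seed = deriveSeed(config$seed, 24L, s))
    }), recursive = FALSE)
    consistency <- classificationConsistency(baseReps,
                                             sweep$selectedPartition)
    reliable <- selectReliableModules(baseReps, sweep$selectedPartition,
                                      k = config$nReliableModules)
    flow <- if (length(tps) >= 2) matchModulesAcrossTimepoints(tpParts) else NULL
    list(sweep = sweep, tpPartitions = tpParts, consistency = consistency,
         reliableModules = reliable, flow = flow)
  })
  writePartition(modules$sweep$selectedPartition,
                 file.path(out, "partition_baseline.tsv"))
  utils::write.csv(
    data.frame(gamma = modules$sweep$gammas,
               mean_nmi = modules$sweep$meanNmi,
               converged = modules$sweep$converged),
    file.path(out, "gamma_sweep.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(roi = names(modules$consistency) %||%
                 seq_along(modules$consistency),
               consistency = as.numeric(modules$consistency)),
    file.path(out, "classification_consistency.csv"), row.names = FALSE)
  if (!is.null(modules$flow)) {
    utils::write.csv(modules$flow$flows, file.path(out, "module_flow.csv"),
                     row.names = FALSE)
  }
  manifest$counts$n_modules_baseline <- nModules(modules$sweep$selectedPartition)
  manifest$counts$selected_gamma <- modules$sweep$selectedGamma

  seg <- stage("segregation", {
    basePart <- modules$sweep$selectedPartition
    siAll <- siTrajectories(mats, basePart, design)
    si3 <- siTrajectories(mats, basePart, design,
                          moduleSubset = modules$reliableModules)
    tab <- siAll
    tab$si_all <- tab$si
    tab$si <- si3$si[match(paste(tab$subject_id, tab$timepoint_label),
                           paste(si3$subject_id, si3$timepoint_label))]
    tab <- flagLowSi(tab, threshold = config$siThreshold)
    tab
  })
  utils::write.csv(seg, file.path(out, "segregation.csv"), row.names = FALSE)
  manifest$counts$segregation_rows <- nrow(seg)
  manifest$counts$n_excluded_low_si <-
    length(unique(seg$subject_id[seg$excluded_flag]))

  metricTab <- stage("metrics", {
    cohortMetricTable(mats, design, densities = config$densities,
                      seed = deriveSeed(config$seed, 31L))
  })
  utils::write.csv(metricTab, file.path(out, "metrics.csv"), row.names = FALSE)
  manifest$counts$metric_rows <- nrow(metricTab)

  stats <- stage("stats", {
    okSubj <- unique(seg$subject_id[!seg$excluded_flag])
    segOk <- seg[seg$subject_id %in% okSubj, ]
    traj <- siTrajectoryAnalysis(segOk)
    lmeSex <- fitLME(segOk, outcome = "si", factor = "sex")
    lmeGroup <- fitLME(segOk, outcome = "si", factor = "group")
    meta <- unique(design[, c("subject_id", "sex", "cohort", "group")])
    mt <- metricTab[metricTab$scope == "global" &
                      metricTab$subject_id %in% okSubj, ]
    mt <- merge(mt, meta, by = "subject_id")
    globalStats <- do.call(rbind, lapply(unique(mt$metric), function(mm) {
      d <- mt[mt$metric == mm & is.finite(mt$value), ]
      d$value <- d$value
      res <- fitLME(d, outcome = "value", factor = "group")
      if (is.null(res$coefficients)) return(NULL)
      tc <- timeContrast(res)
      co <- res$coefficients
      data.frame(metric = mm,
                 age_t = co$t[co$term == ".age"],
                 age_p = co$p[co$term == ".age"],
                 group_t = co$t[grepl("^group", co$term)],
                 group_p = co$p[grepl("^group", co$term)],
                 interaction_t = co$t[grepl(":", co$term)],
                 interaction_p = co$p[grepl(":", co$term)],
                 time_contrast_t = tc$t, time_contrast_p = tc$p,
                 stringsAsFactors = FALSE)
    }))
    nodal <- metricTab[metricTab$scope == "node" &
                         metricTab$metric == "nodal_efficiency" &
                         metricTab$subject_id %in% okSubj, ]
    bil <- combineBilateral(nodal)
    bil <- merge(bil, meta, by = "subject_id")
    bil$unit <- bil$region
    bil$value <- bil$value
    nodalByGroup <- lapply(split(bil, bil$group), function(d) {
      massUnivariateLME(d, factor = "none", alpha = config$fdrAlpha)
    })
    ks <- if (length(nodalByGroup) == 2) {
      ksCompare(nodalByGroup[[1]]$slope_per_day,
                nodalByGroup[[2]]$slope_per_day)
    } else NULL
    list(trajectories = traj, lmeSex = lmeSex, lmeGroup = lmeGroup,
         globalStats = globalStats, nodalByGroup = nodalByGroup, ks = ks)
  })
  utils::write.csv(stats$trajectories, file.path(out, "si_trajectories.csv"),
                   row.names = FALSE)
  if (!is.null(stats$globalStats)) {
    utils::write.csv(stats$globalStats,
                     file.path(out, "global_metric_lme.csv"),
                     row.names = FALSE)
  }
  for (g in names(stats$nodalByGroup)) {
    utils::write.csv(stats$nodalByGroup[[g]],
                     file.path(out, sprintf("nodal_efficiency_lme_%s.csv", g)),
                     row.names = FALSE)
  }
  manifest$counts$trajectory_rows <- nrow(stats$trajectories)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", out)
  invisible(list(design = design, matrices = mats, modules = modules,
                 segregation = seg, metrics = metricTab, stats = stats,
                 manifest = manifest, outDir = out))
}
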