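#' Read and validate an experiment configuration
#'
#' Configuration is a YAML key/value tree; `overrides` (a named, possibly
#' nested list, e.g. from command-line flags) take precedence over file
#' values.  Structural validation happens here; stage-specific checks
#' (e.g. that input files exist) happen in [runExperiment], which lists
#' every violated field at once.
#'
#' @param path YAML file path, or NULL to build a config from `overrides`
#'   alone.
#' @param overrides named list merged over the file values.
#' @return an [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path = NULL, overrides = list()) {
  values <- if (!is.null(path)) yaml::read_yaml(path) else list()
  values <- utils::modifyList(values, overrides)
  new("ExperimentConfig", values = values, path = path %||% "")
}

configGet <- function(config, key, default = NULL) {
  v <- config@values
  for (k in strsplit(key, ".", fixed = TRUE)[[1L]]) {
    if (is.null(v[[k]])) return(default)
    v <- v[[k]]
  }
  v
}

configSettings <- function(config) {
  s <- configGet(config, "settings", list())
  SimulationSettings(durationS = s$durationS %||% 14.5,
                     burnInS = s$burnInS %||% 1,
                     fsHz = s$fsHz %||% 1250,
                     absTol = s$absTol %||% 1e-6,
                     relTol = s$relTol %||% 1e-3)
}

configGrid <- function(config, key, default) {
  g <- configGet(config, key)
  if (is.null(g)) return(default)
  if (is.list(g) && !is.null(g$from))
    return(if (isTRUE(g$log))
             exp(seq(log(g$from), log(g$to), length.out = g$n))
           else seq(g$from, g$to, length.out = g$n))
  as.numeric(g)
}

applyThresholdPolicy <- function(pli, policy) {
  if (is.null(policy) || identical(policy, "none")) return(pli)
  if (identical(policy, "median")) return(medianThresholdPLI(pli))
  if (grepl("^percentile:", policy))
    return(thresholdPLI(pli, as.numeric(sub("^percentile:", "", policy))))
  stop("unknown threshold policy '", policy, "'", call. = FALSE)
}

validateExperimentConfig <- function(config, experiment) {
  bad <- character(0)
  need <- function(cond, what) if (!isTRUE(cond)) bad <<- c(bad, what)
  need(!is.null(configGet(config, "out")), "out: output directory missing")
  if (experiment %in% c("fit", "scaling", "connectotomy")) {
    for (f in c("paths.connectome", "paths.atlas", "paths.pli")) {
      p <- configGet(config, f)
      need(!is.null(p) && file.exists(p),
           paste0(f, ": file missing (", p %||% "unset", ")"))
    }
    p <- configGet(config, "paths.omega")
    need(!is.null(p) && file.exists(p),
         paste0("paths.omega: file missing (", p %||% "unset", ")"))
    need(length(configGrid(config, "grids.K", defaultKGrid())) > 0L,
         "grids.K: empty")
    need(configGet(config, "nIc", 1L) >= 1L, "nIc: must be >= 1")
  }
  if (experiment == "fit")
    need(length(configGrid(config, "grids.lambda", seq(0, 50, by = 5))) > 0L,
         "grids.lambda: empty")
  if (experiment == "connectotomy") {
    for (f in c("paths.masks", "paths.controlPli")) {
      p <- configGet(config, f)
      need(!is.null(p) && file.exists(p),
           paste0(f, ": file missing (", p %||% "unset", ")"))
    }
  }
  if (experiment == "compare") {
    for (f in c("compare.a", "compare.b")) {
      p <- configGet(config, f)
      need(!is.null(p) && file.exists(p),
           paste0(f, ": file missing (", p %||% "unset", ")"))
    }
  }
  if (experiment == "validate")
    need(dir.exists(configGet(config, "validate.dir") %||%
                      configGet(config, "synth.dir") %||% ""),
         "validate.dir: directory missing")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

loadFitInputs <- function(config) {
  atlas <- readAtlas(configGet(config, "paths.atlas"))
  conn <- readConnectome(configGet(config, "paths.connectome"), atlas)
  om <- utils::read.csv(configGet(config, "paths.omega"))
  emp <- readPLI(configGet(config, "paths.pli"), atlas)
  emp <- applyThresholdPolicy(emp, configGet(config, "threshold", "none"))
  list(atlas = atlas, conn = conn, omega = om$omega, emp = emp)
}

#' Run a pipeline experiment end to end
#'
#' Executes one named stage and writes its results, a machine-readable
#' manifest (`manifest.json`: package version, seeds, resolved parameters)
#' and a log (`run.log`, one line per grid record) into the configured
#' output directory.  Stage failures leave partial outputs plus a
#' `FAILED` marker.  Input files are never mutated.  Stages:
#'
#' * `synth` -- generate and write a synthetic cohort.
#' * `fit` -- (K, lambda) grid search against an empirical PLI; writes
#'   `fitgrid.csv`, `curve.csv`, `normalized_coupling.json`.
#' * `scaling` -- grid search at two excitability values; writes the
#'   matched-k optimal-coupling ratio to `scaling.json`.
#' * `connectotomy` -- per-subject functional connectotomy against the
#'   paired control; writes `connectotomy.csv` and `summary.json`.
#' * `compare` -- rank-sum comparison of two samples; writes
#'   `comparison.csv`.
#' * `validate` -- validate a cohort directory.
#'
#' @param config an [ExperimentConfig-class].
#' @param experiment one of "synth", "fit", "scaling", "connectotomy",
#'   "compare", "validate".
#' @return the output directory, invisibly.
#' @export
runExperiment <- function(config,
                          experiment = c("synth", "fit", "scaling",
                                         "connectotomy", "compare",
                                         "validate")) {
  experiment <- match.arg(experiment)
  validateExperimentConfig(config, experiment)
  out <- configGet(config, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(out, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S"), "INFO", ...,
                               "\n", file = logFile, append = TRUE)
  seed <- as.integer(configGet(config, "seed", 1L))
  manifest <- list(package = "hopfconn",
                   version = as.character(utils::packageVersion("hopfconn")),
                   experiment = experiment, seed = seed,
                   config = config@values)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(out, "FAILED")))
  logLine("stage", experiment, "seed", seed)

  if (experiment == "synth") {
    sy <- configGet(config, "synth", list())
    spec <- SyntheticCohortSpec(
      N = sy$N %||% 20L, nControls = sy$nControls %||% 33L,
      nPatients = sy$nPatients %||% 10L, KControl = sy$KControl %||% 8,
      KPatient = sy$KPatient %||% 8, lambdaTrue = sy$lambdaTrue %||% 40,
      maskSizeRange = sy$maskSizeRange %||% c(3L, 3L),
      gain = sy$gain %||% 1.5, epochs = sy$epochs %||% 3L,
      noiseSd = sy$noiseSd %||% 0.02, density = sy$density %||% 0.3,
      seed = seed)
    cohort <- makeCohort(spec, configSettings(config))
    writeCohort(cohort, sy$dir %||% file.path(out, "cohort"))
    manifest$cohortDir <- sy$dir %||% file.path(out, "cohort")
  } else if (experiment == "fit") {
    inp <- loadFitInputs(config)
    grid <- gridSearch(inp$conn, inp$omega, inp$emp,
                       configGrid(config, "grids.K", defaultKGrid()),
                       configGrid(config, "grids.lambda", seq(0, 50, by = 5)),
                       nIc = configGet(config, "nIc", 10L), seed = seed,
                       settings = configSettings(config),
                       C = configGet(config, "model.C", 20),
                       logCell = function(K, lambda, ic, r)
                         logLine("cell K=", K, "lambda=", lambda,
                                 "ic=", ic, "r=", r))
    fitGridTable(grid, file.path(out, "fitgrid.csv"))
    curve <- optimalCouplingCurve(grid)
    utils::write.csv(data.frame(lambda = curve@lambdaValues,
                                meanK = curveMean(curve),
                                sdK = curveSd(curve)),
                     file.path(out, "curve.csv"), row.names = FALSE)
    fit <- tryCatch(
      fitNormalizedCoupling(curve,
                            configGet(config, "lambdaMin", 5)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      jsonlite::write_json(list(k = fit@k, rss = fit@rss,
                                lambdaRange = fit@lambdaRange),
                           file.path(out, "normalized_coupling.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$k <- fit@k
    }
    surf <- meanSurface(grid)
    best <- which(surf == max(surf, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    manifest$bestMeanR <- max(surf, na.rm = TRUE)
    manifest$bestK <- grid@KValues[best[1L]]
    manifest$bestLambda <- grid@lambdaValues[best[2L]]
  } else if (experiment == "scaling") {
    inp <- loadFitInputs(config)
    lams <- c(configGet(config, "scaling.lambdaLow", 10),
              configGet(config, "scaling.lambdaHigh", 40))
    grid <- gridSearch(inp$conn, inp$omega, inp$emp,
                       configGrid(config, "grids.K", defaultKGrid()),
                       lams, nIc = configGet(config, "nIc", 10L),
                       seed = seed, settings = configSettings(config),
                       C = configGet(config, "model.C", 20))
    curve <- optimalCouplingCurve(grid)
    km <- curveMean(curve)
    res <- list(lambdaLow = lams[1L], lambdaHigh = lams[2L],
                meanOptimalKLow = km[1L], meanOptimalKHigh = km[2L],
                ratio = km[2L] / km[1L],
                expectedRatio = sqrt(lams[2L] / lams[1L]))
    jsonlite::write_json(res, file.path(out, "scaling.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$scaling <- res
  } else if (experiment == "connectotomy") {
    inp <- loadFitInputs(config)
    controlEmp <- readPLI(configGet(config, "paths.controlPli"), inp$atlas)
    controlEmp <- applyThresholdPolicy(controlEmp,
                                       configGet(config, "threshold", "none"))
    masks <- readTumorMasks(configGet(config, "paths.masks"), inp$atlas)
    lambdaFixed <- configGet(config, "connectotomy.lambdaFixed", 40)
    nIc <- configGet(config, "nIc", 10L)
    ics <- sampleInitialConditions(nIc, regionCount(inp$conn), seed)
    KGrid <- configGrid(config, "grids.K", defaultKGrid())
    bank <- simulatePLIBank(inp$conn, inp$omega, KGrid, lambdaFixed, ics,
                            settings = configSettings(config),
                            C = configGet(config, "model.C", 20))
    logLine("bank of", length(KGrid), "K x", nIc, "ic simulated")
    allRec <- list()
    comparisons <- list()
    for (m in masks) {
      half <- connectotomyRefit(inp$emp, m, lambdaFixed = lambdaFixed,
                                bank = bank)
      paired <- pairWithControl(half, controlEmp, bank)
      allRec[[m@subjectId]] <- cbind(subject = m@subjectId, paired@records)
      d <- differenceOfChanges(paired)
      if (any(d != 0))
        comparisons[[m@subjectId]] <- wilcoxonSignedRank(d)
      logLine("subject", m@subjectId, "mean diff-of-changes", mean(d))
    }
    utils::write.csv(do.call(rbind, allRec),
                     file.path(out, "connectotomy.csv"), row.names = FALSE)
    if (length(comparisons))
      writeComparisonTable(comparisons, file.path(out, "summary.csv"))
    jsonlite::write_json(
      lapply(allRec, function(r) {
        d <- r$delta[r$arm == "patient"] - r$delta[r$arm == "control"]
        list(meanDifferenceOfChanges = mean(d), n = length(d))
      }),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (experiment == "compare") {
    a <- utils::read.csv(configGet(config, "compare.a"))$value
    b <- utils::read.csv(configGet(config, "compare.b"))$value
    cc <- wilcoxonRankSum(a, b)
    writeComparisonTable(list(comparison = cc),
                         file.path(out, "comparison.csv"))
    manifest$pValue <- cc@pValue
  } else if (experiment == "validate") {
    validateCohortDir(configGet(config, "validate.dir") %||%
                        configGet(config, "synth.dir"))
    manifest$valid <- TRUE
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  logLine("stage", experiment, "complete")
  ok <- TRUE
  invisible(out)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig",
      if (nzchar(object@path)) paste0("(", object@path, ")") else "(in-memory)",
      "with", length(object@values), "top-level keys\n")
})
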