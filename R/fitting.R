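#' Simulate the full PLI pipeline for one parameter set
#'
#' Runs simulate -> band-pass -> instantaneous phase -> PLI with the
#' standard processing: alpha-band (8-12 Hz) zero-phase Butterworth
#' filtering and trimming of `edgeTrimS` seconds at each end of the phase
#' series to suppress filter/Hilbert edge artifacts.
#'
#' @param params a [HopfParameters-class].
#' @param W a [Connectome-class] or weight matrix.
#' @param ic complex initial state vector.
#' @param settings a [SimulationSettings-class].
#' @param band analysis band in Hz (default c(8, 12)).
#' @param edgeTrimS seconds trimmed from each end before the PLI (default
#'   0.5).
#' @return a simulated [PLIMatrix-class].
#' @export
simulatePLI <- function(params, W, ic, settings = SimulationSettings(),
                        band = c(8, 12), edgeTrimS = 0.5) {
  ts <- simulateHopf(params, W, ic, settings)
  ph <- instantaneousPhase(bandpass(ts, band[1L], band[2L]))
  m <- ph@phases
  trim <- round(edgeTrimS * ph@fsHz)
  stopIfNot(nrow(m) > 2L * trim + 2L, "signal too short after edge trimming")
  if (trim > 0L) m <- m[(trim + 1L):(nrow(m) - trim), , drop = FALSE]
  phaseLagIndex(new("PhasePanel", phases = m, fsHz = ph@fsHz,
                    labels = ph@labels, band = ph@band),
                source = "simulated")
}

#' Pearson goodness of fit between simulated and empirical PLI
#'
#' Pearson correlation over the off-diagonal upper-triangle entries of the
#' retained submatrix after excluding `exclude` regions (rows and columns
#' removed from both matrices -- the functional-connectotomy objective).
#' Thresholded zeros are included as data points by default.
#'
#' @param sim,emp [PLIMatrix-class] objects with matching labels.
#' @param exclude integer vector of region indices removed from the
#'   objective (default none).
#' @param includeZeros if FALSE, pairs where `emp` is exactly zero
#'   (thresholded away) are dropped from the correlation.
#' @return Pearson correlation r.
#' @export
goodnessOfFit <- function(sim, emp, exclude = integer(0),
                          includeZeros = TRUE) {
  if (!identical(sim@labels, emp@labels))
    stop("simulated and empirical PLI labels differ", call. = FALSE)
  n <- length(sim@labels)
  keep <- setdiff(seq_len(n), as.integer(exclude))
  if (length(keep) < 3L)
    stop("fewer than 3 regions retained; objective undefined", call. = FALSE)
  a <- upperTriValues(sim@values[keep, keep, drop = FALSE])
  b <- upperTriValues(emp@values[keep, keep, drop = FALSE])
  if (!includeZeros) {
    sel <- b != 0
    a <- a[sel]
    b <- b[sel]
  }
  if (length(a) < 3L)
    stop("fewer than 3 region pairs retained", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in PLI entries; correlation undefined", call. = FALSE)
  stats::cor(a, b)
}

#' Goodness of fit of one (K, lambda) cell over initial conditions
#'
#' For each initial condition: simulate, band-pass, extract phases,
#' compute the PLI, and correlate with the empirical PLI.  Degenerate
#' cells (zero-variance PLI) yield NA with a warning rather than an error,
#' so grid scans over strongly synchronized regimes remain well defined.
#'
#' @param K,lambda the cell's coupling and excitability.
#' @param W a [Connectome-class].
#' @param omega angular natural frequencies (rad/s).
#' @param emp empirical [PLIMatrix-class].
#' @param ics list of complex initial conditions.
#' @param settings a [SimulationSettings-class].
#' @param exclude region indices excluded from the objective.
#' @param C structural scaling (default 20).
#' @param includeZeros passed to [goodnessOfFit].
#' @return numeric vector of r, one per initial condition.
#' @export
evaluateCell <- function(K, lambda, W, omega, emp, ics,
                         settings = SimulationSettings(),
                         exclude = integer(0), C = 20, includeZeros = TRUE) {
  params <- HopfParameters(K = K, lambda = lambda, omega = omega, C = C)
  vapply(seq_along(ics), function(i) {
    sim <- tryCatch(
      simulatePLI(params, W, ics[[i]], settings),
      error = function(e) stop("simulation failed at (K=", K, ", lambda=",
                               lambda, ", ic=", i, "): ", conditionMessage(e),
                               call. = FALSE))
    tryCatch(
      goodnessOfFit(sim, emp, exclude = exclude, includeZeros = includeZeros),
      error = function(e) {
        warning("degenerate objective at (K=", K, ", lambda=", lambda,
                ", ic=", i, "): ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }, numeric(1))
}

#' Two-dimensional (K, lambda) grid search
#'
#' Fills every grid cell with the same seeded initial-condition ensemble
#' (shared across cells, so per-initial-condition comparisons between
#' cells are paired) and records the Pearson goodness of fit per cell and
#' initial condition.
#'
#' @param W a [Connectome-class].
#' @param omega angular natural frequencies (rad/s).
#' @param emp empirical [PLIMatrix-class].
#' @param KGrid,lambdaGrid nonempty parameter grids (sorted internally).
#' @param nIc number of initial conditions (>= 1).
#' @param seed seed generating the initial-condition ensemble.
#' @param settings a [SimulationSettings-class].
#' @param exclude region indices excluded from the objective.
#' @param C structural scaling (default 20).
#' @param includeZeros passed to [goodnessOfFit].
#' @param logCell optional function(K, lambda, ic, r) called per record.
#' @return a [FitGrid-class].
#' @export
gridSearch <- function(W, omega, emp, KGrid, lambdaGrid, nIc, seed,
                       settings = SimulationSettings(), exclude = integer(0),
                       C = 20, includeZeros = TRUE, logCell = NULL) {
  stopIfNot(length(KGrid) > 0L && length(lambdaGrid) > 0L, "empty grid")
  stopIfNot(nIc >= 1L, "nIc must be >= 1")
  KGrid <- sort(unique(as.numeric(KGrid)))
  lambdaGrid <- sort(unique(as.numeric(lambdaGrid)))
  ics <- sampleInitialConditions(nIc, regionCount(W), seed)
  r <- array(NA_real_, dim = c(length(KGrid), length(lambdaGrid), nIc))
  for (li in seq_along(lambdaGrid)) {
    for (ki in seq_along(KGrid)) {
      rs <- evaluateCell(KGrid[ki], lambdaGrid[li], W, omega, emp, ics,
                         settings = settings, exclude = exclude, C = C,
                         includeZeros = includeZeros)
      r[ki, li, ] <- rs
      if (!is.null(logCell))
        for (i in seq_len(nIc)) logCell(KGrid[ki], lambdaGrid[li], i, rs[i])
    }
  }
  new("FitGrid", KValues = KGrid, lambdaValues = lambdaGrid, r = r,
      seed = as.integer(seed))
}

#' Default log-spaced coupling grid
#'
#' 31 points log-spaced over [0.1, 30].
#'
#' @param n number of points (default 31).
#' @param from,to grid bounds (defaults 0.1 and 30).
#' @return numeric vector.
#' @export
defaultKGrid <- function(n = 31L, from = 0.1, to = 30) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Optimal coupling per excitability
#'
#' For every lambda and every initial condition, the K on the grid
#' maximizing r; ties break toward the smallest K (the weakest coupling
#' consistent with the optimum).  Initial conditions whose whole K column
#' is NA yield NA.
#'
#' @param grid a filled [FitGrid-class].
#' @return a [CouplingCurve-class].
#' @export
optimalCouplingCurve <- function(grid) {
  nL <- length(grid@lambdaValues)
  nIc <- dim(grid@r)[3L]
  opt <- matrix(NA_real_, nL, nIc)
  for (li in seq_len(nL)) {
    for (ii in seq_len(nIc)) {
      col <- grid@r[, li, ii]
      if (all(is.na(col))) next
      # which.max returns the first maximum; KValues ascending => smallest K
      opt[li, ii] <- grid@KValues[which.max(col)]
    }
  }
  rownames(opt) <- as.character(grid@lambdaValues)
  new("CouplingCurve", lambdaValues = grid@lambdaValues, optimalK = opt,
      KValues = grid@KValues)
}

#' Fit the normalized coupling strength k in K = k sqrt(lambda)
#'
#' Closed-form least squares through the origin on (sqrt(lambda), mean
#' optimal K): k = sum(Kbar * sqrt(lambda)) / sum(lambda).  Excitability
#' values below `lambdaMin` are excluded, since the square-root scaling
#' fails near and below the bifurcation.
#'
#' @param curve a [CouplingCurve-class].
#' @param lambdaMin smallest excitability included (default 5).
#' @return a [NormalizedCouplingFit-class].
#' @export
fitNormalizedCoupling <- function(curve, lambdaMin = 5) {
  lam <- curve@lambdaValues
  keep <- lam >= lambdaMin & lam > 0
  if (!any(keep))
    stop("no positive excitability values at or above lambdaMin", call. = FALSE)
  lam <- lam[keep]
  Kbar <- rowMeans(curve@optimalK[keep, , drop = FALSE], na.rm = TRUE)
  if (anyNA(Kbar))
    stop("mean optimal coupling undefined for some lambda", call. = FALSE)
  k <- sum(Kbar * sqrt(lam)) / sum(lam)
  rss <- sum((Kbar - k * sqrt(lam))^2)
  new("NormalizedCouplingFit", k = k, rss = rss, lambdaRange = range(lam))
}

#' Select the optimal empirical threshold
#'
#' Runs a (typically reduced) grid search for each candidate percentile
#' threshold of the raw empirical PLI and returns the threshold whose best
#' mean goodness of fit is largest; ties break toward the smallest
#' threshold.
#'
#' @param empRaw unthresholded empirical [PLIMatrix-class].
#' @param W,omega,KGrid,lambdaGrid,nIc,seed,settings,C as in [gridSearch].
#' @param thresholdGrid percentages to try (all < 100).
#' @return the selected percentage, with the per-threshold best mean r in
#'   attribute `"bestR"`.
#' @export
selectOptimalThreshold <- function(empRaw, W, omega, thresholdGrid, KGrid,
                                   lambdaGrid, nIc, seed,
                                   settings = SimulationSettings(), C = 20) {
  stopIfNot(length(thresholdGrid) > 0L, "empty threshold grid")
  stopIfNot(all(thresholdGrid < 100), "thresholds must be < 100")
  thresholdGrid <- sort(thresholdGrid)
  best <- vapply(thresholdGrid, function(p) {
    empT <- thresholdPLI(empRaw, p)
    g <- gridSearch(W, omega, empT, KGrid, lambdaGrid, nIc, seed,
                    settings = settings, C = C)
    max(apply(g@r, c(1L, 2L), mean, na.rm = TRUE), na.rm = TRUE)
  }, numeric(1))
  structure(thresholdGrid[which.max(best)],
            bestR = stats::setNames(best, thresholdGrid))
}

#' @rdname fitgrid-accessors
#' @name fitgrid-accessors
#' @title Accessors for fit grids and coupling curves
#' @param x a [FitGrid-class] or [CouplingCurve-class].
#' @return `meanSurface`: matrix (K x lambda) of mean r over initial
#'   conditions; `curveMean`/`curveSd`: per-lambda mean/sd of optimal K.
NULL

#' @rdname fitgrid-accessors
setMethod("meanSurface", "FitGrid", function(x) {
  m <- apply(x@r, c(1L, 2L), mean, na.rm = TRUE)
  dimnames(m) <- list(as.character(x@KValues), as.character(x@lambdaValues))
  m
})

#' @rdname fitgrid-accessors
setMethod("curveMean", "CouplingCurve", function(x)
  rowMeans(x@optimalK, na.rm = TRUE))

#' @rdname fitgrid-accessors
setMethod("curveSd", "CouplingCurve", function(x)
  apply(x@optimalK, 1L, stats::sd, na.rm = TRUE))

setMethod("show", "FitGrid", function(object) {
  cat("FitGrid:", length(object@KValues), "K x",
      length(object@lambdaValues), "lambda x", dim(object@r)[3L],
      "initial conditions (seed", object@seed, ")\n")
  m <- meanSurface(object)
  i <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  cat("  best mean r =", signif(max(m, na.rm = TRUE), 4), "at K =",
      signif(object@KValues[i[1L]], 4), ", lambda =",
      object@lambdaValues[i[2L]], "\n")
})

setMethod("show", "CouplingCurve", function(object) {
  cat("CouplingCurve over", length(object@lambdaValues), "lambda values,",
      ncol(object@optimalK), "initial conditions\n")
  print(data.frame(lambda = object@lambdaValues,
                   meanK = signif(curveMean(object), 4),
                   sdK = signif(curveSd(object), 4)))
})

setMethod("show", "NormalizedCouplingFit", function(object) {
  cat("Normalized coupling fit: k =", signif(object@k, 4), "(rss",
      signif(object@rss, 3), ", lambda in [",
      object@lambdaRange[1L], ",", object@lambdaRange[2L], "])\n")
})

#' Serialize a fit grid as one row per (K, lambda, ic)
#'
#' @param grid a [FitGrid-class].
#' @param path optional CSV path; when NULL the data.frame is returned
#'   only.
#' @return data.frame with columns K, lambda, ic, seed, r.
#' @export
fitGridTable <- function(grid, path = NULL) {
  d <- dim(grid@r)
  df <- expand.grid(K = grid@KValues, lambda = grid@lambdaValues,
                    ic = seq_len(d[3L]))
  df$seed <- grid@seed
  df$r <- as.vector(grid@r)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
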