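#' @import methods
NULL

#' RegionAtlas: ordered region labels with optional 3-D centroids
#'
#' Holds the parcellation used throughout the package: an ordered vector of
#' unique region names and, optionally, one 3-D centroid (in mm) per region.
#' Region order is defined by the atlas; every matrix in the package must
#' match it (no silent reordering).
#'
#' @slot labels character vector of unique region names (length N >= 2).
#' @slot centroids numeric matrix with 0 rows (absent) or N rows and 3
#'   columns of centroid coordinates.
#' @export
setClass("RegionAtlas",
  slots = c(labels = "character", centroids = "matrix"))

setValidity("RegionAtlas", function(object) {
  msg <- character(0)
  if (length(object@labels) < 2L)
    msg <- c(msg, "atlas needs at least 2 regions")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "region labels must be unique")
  cen <- object@centroids
  if (nrow(cen) > 0L) {
    if (nrow(cen) != length(object@labels) || ncol(cen) != 3L)
      msg <- c(msg, "centroids must be an N x 3 matrix")
    if (!all(is.finite(cen)))
      msg <- c(msg, "centroids must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Connectome: nonnegative symmetric weighted structural network
#'
#' The network substrate of the whole-brain model: an N x N matrix of
#' nonnegative weights w_ij (zero diagonal, symmetric to 1e-9) bound to a
#' [RegionAtlas].
#'
#' @slot W numeric N x N weight matrix.
#' @slot atlas the [RegionAtlas] defining region order.
#' @export
setClass("Connectome",
  slots = c(W = "matrix", atlas = "RegionAtlas"))

setValidity("Connectome", function(object) {
  W <- object@W
  n <- length(object@atlas@labels)
  msg <- character(0)
  if (nrow(W) != n || ncol(W) != n)
    msg <- c(msg, "W must be N x N with N matching the atlas")
  if (!all(is.finite(W)))
    msg <- c(msg, "W must be finite")
  else {
    if (any(W < 0)) msg <- c(msg, "weights must be nonnegative")
    if (max(abs(W - t(W))) > 1e-9) msg <- c(msg, "W must be symmetric (tol 1e-9)")
    if (any(diag(W) != 0)) msg <- c(msg, "diagonal must be zero")
    if (!any(W > 0)) msg <- c(msg, "W must have at least one positive entry")
  }
  if (length(msg)) msg else TRUE
})

#' TumorMask: the set of tumor regions of one subject
#'
#' @slot subjectId subject identifier.
#' @slot regions sorted integer vector of region indices (1-based).
#' @slot nRegions the atlas region count the indices refer to.
#' @export
setClass("TumorMask",
  slots = c(subjectId = "character", regions = "integer", nRegions = "integer"))

setValidity("TumorMask", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  r <- object@regions
  if (length(r) && (any(r < 1L) || any(r > object@nRegions)))
    msg <- c(msg, "region indices out of range")
  if (anyDuplicated(r)) msg <- c(msg, "region indices must be unique")
  if (length(msg)) msg else TRUE
})

#' HopfParameters: parameters of the Hopf whole-brain model
#'
#' Parameters of dz_i/dt = z_i(lambda + i omega_i - |z_i|^2)
#'                          + g_i K tanh(C sum_j w_ij x_j):
#' global coupling strength K, global excitability (Hopf bifurcation
#' parameter) lambda, structural scaling C, angular natural frequencies
#' omega (rad/s), and an optional per-region coupling gain g (all 1 for the
#' plain model; >1 on tumor regions in the synthetic patient generator).
#'
#' @slot K global coupling strength, >= 0.
#' @slot lambda global excitability parameter (any real).
#' @slot Cscale structural scaling C, > 0 (default 20).
#' @slot omega angular natural frequencies in rad/s, one per region, > 0.
#' @slot gain per-region coupling input gain, > 0.
#' @export
setClass("HopfParameters",
  slots = c(K = "numeric", lambda = "numeric", Cscale = "numeric",
            omega = "numeric", gain = "numeric"))

setValidity("HopfParameters", function(object) {
  msg <- character(0)
  if (length(object@K) != 1L || object@K < 0) msg <- c(msg, "K must be a single value >= 0")
  if (length(object@lambda) != 1L || !is.finite(object@lambda))
    msg <- c(msg, "lambda must be a single finite value")
  if (length(object@Cscale) != 1L || object@Cscale <= 0) msg <- c(msg, "C must be > 0")
  if (!length(object@omega) || any(object@omega <= 0))
    msg <- c(msg, "omega must be positive (rad/s)")
  if (length(object@gain) != length(object@omega) || any(object@gain <= 0))
    msg <- c(msg, "gain must be positive and match omega in length")
  if (length(msg)) msg else TRUE
})

#' SimulationSettings: integration and sampling protocol
#'
#' Defaults follow the standard MEG-matched protocol: 14.5 s simulated,
#' first 1 s discarded as transient, 1250 Hz output sampling, adaptive
#' Runge-Kutta 4(5) at absolute tolerance 1e-6 and relative tolerance 1e-3.
#'
#' @slot durationS total simulated time (s).
#' @slot burnInS initial transient discarded (s).
#' @slot fsHz output sampling frequency (Hz).
#' @slot absTol absolute tolerance of the adaptive integrator.
#' @slot relTol relative tolerance of the adaptive integrator.
#' @export
setClass("SimulationSettings",
  slots = c(durationS = "numeric", burnInS = "numeric", fsHz = "numeric",
            absTol = "numeric", relTol = "numeric"))

setValidity("SimulationSettings", function(object) {
  msg <- character(0)
  if (!(object@durationS > object@burnInS && object@burnInS > 0))
    msg <- c(msg, "need durationS > burnInS > 0")
  if (object@fsHz <= 0) msg <- c(msg, "fsHz must be positive")
  if (object@absTol <= 0 || object@relTol <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (length(msg)) msg else TRUE
})

#' TimeSeriesPanel: multichannel real-valued signals
#'
#' T x N matrix of regional signals (the real parts x_i of the oscillator
#' states, standing in for MEG), with sampling rate and region labels.
#' After band-pass filtering the pass band is recorded in `band`.
#'
#' @slot values numeric T x N matrix.
#' @slot fsHz sampling frequency (Hz).
#' @slot labels region labels (length N).
#' @slot band numeric(0), or c(low, high) in Hz after filtering.
#' @export
setClass("TimeSeriesPanel",
  slots = c(values = "matrix", fsHz = "numeric", labels = "character",
            band = "numeric"))

setValidity("TimeSeriesPanel", function(object) {
  msg <- character(0)
  if (ncol(object@values) != length(object@labels))
    msg <- c(msg, "number of columns must match labels")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (object@fsHz <= 0) msg <- c(msg, "fsHz must be positive")
  if (!length(object@band) %in% c(0L, 2L))
    msg <- c(msg, "band must be empty or c(low, high)")
  if (length(msg)) msg else TRUE
})

#' PhasePanel: instantaneous phases of band-limited signals
#'
#' @slot phases numeric T x N matrix of phases in (-pi, pi].
#' @slot fsHz sampling frequency (Hz).
#' @slot labels region labels.
#' @slot band the analysis band in Hz (may be empty if unknown).
#' @export
setClass("PhasePanel",
  slots = c(phases = "matrix", fsHz = "numeric", labels = "character",
            band = "numeric"))

setValidity("PhasePanel", function(object) {
  msg <- character(0)
  p <- object@phases
  if (ncol(p) != length(object@labels))
    msg <- c(msg, "number of columns must match labels")
  if (!all(is.finite(p)) || any(p <= -pi - 1e-12) || any(p > pi + 1e-12))
    msg <- c(msg, "phases must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' PLIMatrix: phase-lag-index functional connectivity
#'
#' Symmetric N x N matrix of phase-lag indices in [0, 1] with zero
#' diagonal.  `source` records whether it came from a simulation or from
#' empirical signals; `threshold` records thresholding provenance (empty
#' list if unthresholded, else `list(kind = "percentile"|"median",
#' level = ...)`).
#'
#' @slot values numeric N x N matrix.
#' @slot labels region labels.
#' @slot source "simulated" or "empirical".
#' @slot threshold list(), or list(kind =, level =).
#' @export
setClass("PLIMatrix",
  slots = c(values = "matrix", labels = "character", source = "character",
            threshold = "list"))

setValidity("PLIMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  msg <- character(0)
  if (nrow(v) != n || ncol(v) != n) msg <- c(msg, "values must be N x N")
  if (!all(is.finite(v))) msg <- c(msg, "values must be finite")
  else {
    if (any(v < -1e-12) || any(v > 1 + 1e-12)) msg <- c(msg, "entries must be in [0, 1]")
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  }
  if (!object@source %in% c("simulated", "empirical"))
    msg <- c(msg, "source must be 'simulated' or 'empirical'")
  if (length(msg)) msg else TRUE
})

#' SpectralPeakTable: per-region spectral peaks with acceptance flags
#'
#' A candidate peak (the frequency above 4 Hz with the highest Welch
#' spectral density) per region, and whether it was accepted (density at
#' least twice the background level).
#'
#' @slot labels region labels.
#' @slot peakHz candidate peak frequency per region (Hz).
#' @slot accepted logical acceptance flag per region.
#' @export
setClass("SpectralPeakTable",
  slots = c(labels = "character", peakHz = "numeric", accepted = "logical"))

setValidity("SpectralPeakTable", function(object) {
  msg <- character(0)
  n <- length(object@labels)
  if (length(object@peakHz) != n || length(object@accepted) != n)
    msg <- c(msg, "peakHz and accepted must match labels in length")
  if (any(object@accepted & !(object@peakHz > 4), na.rm = TRUE))
    msg <- c(msg, "accepted peaks must be > 4 Hz")
  if (length(msg)) msg else TRUE
})

#' FitGrid: goodness-of-fit surface over (K, lambda) and initial conditions
#'
#' Pearson goodness of fit r for every (K, lambda) cell, one value per
#' initial condition; the same seeded initial-condition ensemble is shared
#' across all cells so cells are paired.  Cells whose simulated PLI is
#' degenerate (zero variance) hold NA.
#'
#' @slot KValues ascending coupling grid.
#' @slot lambdaValues ascending excitability grid.
#' @slot r array of dim (K, lambda, ic) with r in [-1, 1] or NA.
#' @slot seed the seed that generated the initial-condition ensemble.
#' @export
setClass("FitGrid",
  slots = c(KValues = "numeric", lambdaValues = "numeric", r = "array",
            seed = "integer"))

setValidity("FitGrid", function(object) {
  msg <- character(0)
  d <- dim(object@r)
  if (length(d) != 3L || d[1] != length(object@KValues) ||
      d[2] != length(object@lambdaValues))
    msg <- c(msg, "r must have dim (K, lambda, ic)")
  rr <- object@r[is.finite(object@r)]
  if (length(rr) && (any(rr < -1 - 1e-9) || any(rr > 1 + 1e-9)))
    msg <- c(msg, "r must lie in [-1, 1]")
  if (is.unsorted(object@KValues, strictly = TRUE))
    msg <- c(msg, "KValues must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' CouplingCurve: optimal coupling per excitability over initial conditions
#'
#' @slot lambdaValues the excitability grid.
#' @slot optimalK matrix (lambda x ic) of per-initial-condition optimal K.
#' @slot KValues the coupling grid the optima were drawn from.
#' @export
setClass("CouplingCurve",
  slots = c(lambdaValues = "numeric", optimalK = "matrix", KValues = "numeric"))

setValidity("CouplingCurve", function(object) {
  msg <- character(0)
  if (nrow(object@optimalK) != length(object@lambdaValues))
    msg <- c(msg, "optimalK must have one row per lambda")
  ok <- object@optimalK[is.finite(object@optimalK)]
  if (length(ok) && !all(ok %in% object@KValues))
    msg <- c(msg, "optimal K values must come from the K grid")
  if (length(msg)) msg else TRUE
})

#' NormalizedCouplingFit: least-squares fit of K = k sqrt(lambda)
#'
#' @slot k fitted normalized coupling strength (>= 0).
#' @slot rss residual sum of squares of the regression.
#' @slot lambdaRange range of excitability values used.
#' @export
setClass("NormalizedCouplingFit",
  slots = c(k = "numeric", rss = "numeric", lambdaRange = "numeric"))

#' ConnectotomyOutcome: optimal-coupling changes induced by masking
#'
#' Per-initial-condition optimal coupling before and after removing the
#' mask regions from the fitting objective, for the patient arm and (after
#' [pairWithControl]) a seed-paired control arm.
#'
#' @slot subjectId subject identifier.
#' @slot mask the [TumorMask] removed from the objective.
#' @slot lambdaFixed the fixed excitability of the 1-D coupling scan.
#' @slot records data.frame with columns ic, arm, KBefore, KAfter, delta.
#' @export
setClass("ConnectotomyOutcome",
  slots = c(subjectId = "character", mask = "TumorMask",
            lambdaFixed = "numeric", records = "data.frame"))

setValidity("ConnectotomyOutcome", function(object) {
  msg <- character(0)
  need <- c("ic", "arm", "KBefore", "KAfter", "delta")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, "records must have columns ic, arm, KBefore, KAfter, delta")
  else if (nrow(object@records) &&
           max(abs(object@records$delta -
                   (object@records$KAfter - object@records$KBefore))) > 1e-12)
    msg <- c(msg, "delta must equal KAfter - KBefore")
  if (length(msg)) msg else TRUE
})

#' CohortComparison: a nonparametric two-sample comparison
#'
#' @slot test "rank_sum" or "signed_rank".
#' @slot statistic the test statistic.
#' @slot pValue two-sided p-value.
#' @slot meanDifference mean(a) - mean(b) (rank-sum) or mean of the paired
#'   differences (signed-rank).
#' @slot n sample sizes.
#' @export
setClass("CohortComparison",
  slots = c(test = "character", statistic = "numeric", pValue = "numeric",
            meanDifference = "numeric", n = "integer"))

setValidity("CohortComparison", function(object) {
  msg <- character(0)
  if (!object@test %in% c("rank_sum", "signed_rank"))
    msg <- c(msg, "test must be 'rank_sum' or 'signed_rank'")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortSpec: design of a synthetic two-cohort study
#'
#' Defaults emulate the study design the generator stands in for: two
#' cohorts (33 controls, 10 patients) sharing one connectome and one
#' alpha-band natural-frequency profile, subject-level "empirical" PLI
#' generated by the model itself at known ground truth (K* = 8,
#' lambda* = 40) from 3 epochs with observation noise (sd 0.02), and
#' patients carrying a coupling gain of 1.5 on 3 tumor regions.
#'
#' @slot N region count (default 20).
#' @slot nControls,nPatients cohort sizes.
#' @slot KControl,KPatient ground-truth global coupling per arm.
#' @slot lambdaTrue ground-truth excitability.
#' @slot maskSizeRange c(min, max) tumor-mask size.
#' @slot gain tumor coupling gain (>= 1).
#' @slot epochs epochs per subject.
#' @slot noiseSd observation noise sd on PLI entries.
#' @slot density edge density of the synthetic connectome.
#' @slot seed master seed; all other seeds derive from it.
#' @export
setClass("SyntheticCohortSpec",
  slots = c(N = "integer", nControls = "integer", nPatients = "integer",
            KControl = "numeric", KPatient = "numeric", lambdaTrue = "numeric",
            maskSizeRange = "integer", gain = "numeric", epochs = "integer",
            noiseSd = "numeric", density = "numeric", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character(0)
  if (object@N < 4L) msg <- c(msg, "N must be >= 4")
  if (object@gain < 1) msg <- c(msg, "gain must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(object@maskSizeRange) != 2L ||
      object@maskSizeRange[1] < 1L ||
      object@maskSizeRange[2] > object@N - 3L ||
      object@maskSizeRange[1] > object@maskSizeRange[2])
    msg <- c(msg, "maskSizeRange must be within [1, N-3] and increasing")
  if (object@density <= 0 || object@density > 1)
    msg <- c(msg, "density must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated two-cohort data set
#'
#' @slot connectome shared [Connectome] (with centroids).
#' @slot omega shared angular natural frequencies (rad/s).
#' @slot subjects list of per-subject records: id, pli ([PLIMatrix]),
#'   mask ([TumorMask] or NULL), truth (list of generating parameters).
#' @slot spec the [SyntheticCohortSpec] that produced the cohort.
#' @export
setClass("SyntheticCohort",
  slots = c(connectome = "Connectome", omega = "numeric", subjects = "list",
            spec = "SyntheticCohortSpec"))

#' ExperimentConfig: validated configuration of a pipeline run
#'
#' @slot values nested named list of configuration values.
#' @slot path the file the configuration was loaded from ("" if in-memory).
#' @export
setClass("ExperimentConfig",
  slots = c(values = "list", path = "character"))
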