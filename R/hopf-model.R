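#' Construct Hopf whole-brain model parameters
#'
#' @param K global coupling strength (>= 0).
#' @param lambda global excitability (Hopf bifurcation) parameter.
#' @param omega angular natural frequencies in rad/s (one per region).
#'   Use `2 * pi * fHz` to convert peak frequencies in Hz.
#' @param C structural scaling of the connectome (default 20; the fit is
#'   insensitive to C once the sigmoid saturates).
#' @param gain optional per-region coupling input gain (default all 1).
#' @return a [HopfParameters-class].
#' @examples
#' HopfParameters(K = 8, lambda = 40, omega = rep(2 * pi * 10, 20))
#' @export
HopfParameters <- function(K, lambda, omega, C = 20, gain = NULL) {
  if (is.null(gain)) gain <- rep(1, length(omega))
  new("HopfParameters", K = as.numeric(K), lambda = as.numeric(lambda),
      Cscale = as.numeric(C), omega = as.numeric(omega),
      gain = as.numeric(gain))
}

#' Construct simulation settings
#'
#' @param durationS total simulated time in seconds (default 14.5).
#' @param burnInS initial transient discarded in seconds (default 1).
#' @param fsHz output sampling frequency in Hz (default 1250).
#' @param absTol,relTol adaptive-integrator tolerances (defaults 1e-6, 1e-3).
#' @return a [SimulationSettings-class].
#' @export
SimulationSettings <- function(durationS = 14.5, burnInS = 1, fsHz = 1250,
                               absTol = 1e-6, relTol = 1e-3) {
  new("SimulationSettings", durationS = as.numeric(durationS),
      burnInS = as.numeric(burnInS), fsHz = as.numeric(fsHz),
      absTol = as.numeric(absTol), relTol = as.numeric(relTol))
}

#' Drift of the Hopf whole-brain model
#'
#' Evaluates dz_i/dt = z_i (lambda + i omega_i - |z_i|^2)
#' + g_i K tanh(C sum_j w_ij x_j), where x_j = Re(z_j): the Hopf normal
#' form (Stuart-Landau oscillator) per region plus a sigmoidal coupling
#' through the real parts only.  The coupling term is real, so it enters
#' the real part of the derivative.
#'
#' @param z complex state vector (length N).
#' @param params a [HopfParameters-class].
#' @param W a [Connectome-class] or plain N x N weight matrix.
#' @return complex derivative vector dz/dt.
#' @export
hopfDrift <- function(z, params, W) {
  if (!all(is.finite(Re(z))) || !all(is.finite(Im(z))))
    stop("non-finite state", call. = FALSE)
  Wm <- if (is(W, "Connectome")) W@W else as.matrix(W)
  stopIfNot(length(z) == nrow(Wm), "state length must match W")
  stopIfNot(length(params@omega) == length(z), "omega length must match state")
  coupling <- params@gain * params@K * tanh(params@Cscale * as.vector(Wm %*% Re(z)))
  z * (params@lambda + 1i * params@omega - Mod(z)^2) + coupling
}

#' Sample random initial conditions
#'
#' Each z_i(0) has independent real and imaginary parts drawn uniformly
#' from [-1, 1]; the ensemble is reproducible given the seed.
#'
#' @param n number of initial conditions.
#' @param N number of regions.
#' @param seed RNG seed.
#' @return list of `n` complex vectors of length `N`.
#' @export
sampleInitialConditions <- function(n, N, seed) {
  stopIfNot(n >= 1, "n must be >= 1")
  withSeed(seed, lapply(seq_len(n), function(i)
    complex(real = stats::runif(N, -1, 1),
            imaginary = stats::runif(N, -1, 1))))
}

#' Simulate the Hopf whole-brain model
#'
#' Integrates the model with adaptive Runge-Kutta 4(5) (Dormand-Prince,
#' via deSolve with a compiled right-hand side) at the settings'
#' tolerances, samples the solution on a uniform grid at `fsHz`, discards
#' the burn-in, and returns the real parts x_i(t) (the simulated MEG-like
#' signals).  With `full = TRUE` the imaginary parts are returned as well,
#' which gives access to the oscillation amplitude |z|.
#'
#' @param params a [HopfParameters-class].
#' @param W a [Connectome-class] or plain weight matrix (a single isolated
#'   node may pass `matrix(0, 1, 1)`).
#' @param ic complex initial state vector.
#' @param settings a [SimulationSettings-class].
#' @param full if TRUE, return `list(x = TimeSeriesPanel, y = matrix)`.
#' @param engine "native" (the package's compiled Dormand-Prince RK45 with
#'   dense output; default) or "deSolve" (the same method through
#'   deSolve's "ode45"); the two agree to within the integration
#'   tolerances and the deSolve route serves as an independent reference.
#' @return a [TimeSeriesPanel-class] (or a list, see `full`).
#' @export
simulateHopf <- function(params, W, ic, settings = SimulationSettings(),
                         full = FALSE, engine = c("native", "deSolve")) {
  engine <- match.arg(engine)
  Wm <- if (is(W, "Connectome")) W@W else as.matrix(W)
  labels <- if (is(W, "Connectome")) regionLabels(W) else
    sprintf("R%02d", seq_len(nrow(Wm)))
  N <- nrow(Wm)
  stopIfNot(length(ic) == N, "initial condition length must match W")
  stopIfNot(length(params@omega) == N, "omega length must match W")
  if (settings@fsHz <= max(params@omega) / pi)
    stop("sampling frequency below Nyquist for the fastest oscillator",
         call. = FALSE)
  pack <- c(N, params@K, params@lambda, params@Cscale, params@omega, params@gain,
            as.vector(Wm))
  .C("hopf_set_parms", as.double(pack), as.integer(length(pack)),
     PACKAGE = "hopfconn")
  times <- seq(0, settings@durationS, by = 1 / settings@fsHz)
  y0 <- c(Re(ic), Im(ic))
  if (engine == "native") {
    nt <- length(times)
    # cap the step at the output interval: untethered steps at the loose
    # default tolerances drift measurably on fast limit cycles
    res <- .C("hopf_simulate", as.double(y0), as.integer(2L * N),
              times = as.double(times), as.integer(nt),
              as.double(settings@absTol), as.double(settings@relTol),
              as.double(1 / settings@fsHz),
              out = double(nt * 2L * N), status = integer(1L),
              PACKAGE = "hopfconn")
    if (res$status != 0L || !all(is.finite(res$out)))
      stop("integration failed (status ", res$status, ") near t = ",
           signif(res$times[1L], 4), " s", call. = FALSE)
    sol <- matrix(res$out, nt, 2L * N)
  } else {
    raw <- deSolve::ode(y = y0, times = times, func = "hopf_derivs",
                        parms = NULL, dllname = "hopfconn", initfunc = NULL,
                        method = "ode45", atol = settings@absTol,
                        rtol = settings@relTol)
    if (nrow(raw) < length(times) || !all(is.finite(raw)))
      stop("integration failed near t = ",
           signif(raw[nrow(raw), 1L], 4), " s", call. = FALSE)
    sol <- raw[, -1L, drop = FALSE]
  }
  keep <- times >= settings@burnInS - 1e-9
  x <- sol[keep, seq_len(N), drop = FALSE]
  dimnames(x) <- list(NULL, labels)
  panel <- new("TimeSeriesPanel", values = x, fsHz = settings@fsHz,
               labels = labels, band = numeric(0))
  if (!full) return(panel)
  yim <- sol[keep, N + seq_len(N), drop = FALSE]
  dimnames(yim) <- list(NULL, labels)
  list(x = panel, y = yim)
}

#' Normalized coupling strength
#'
#' The ratio k = K / sqrt(lambda) that, for excitability well above the
#' bifurcation, solely determines the model's phase dynamics: the coupling
#' strength measured against the radius sqrt(lambda) of the local limit
#' cycle.
#'
#' @param K global coupling strength.
#' @param lambda global excitability (> 0).
#' @return k = K / sqrt(lambda).
#' @export
normalizedCoupling <- function(K, lambda) {
  if (any(lambda <= 0))
    stop("normalized coupling requires lambda > 0", call. = FALSE)
  K / sqrt(lambda)
}

#' Rescale parameters to a different excitability at matched k
#'
#' Returns parameters with `lambda = lambdaTarget` and K scaled by
#' sqrt(lambdaTarget / lambda) so the normalized coupling strength is
#' preserved; omega, C, and gain are unchanged.  Together with
#' [rescaleInitialCondition] this produces the matched parameter/state
#' pairs under which the phase dynamics (and hence PLI) are invariant.
#'
#' @param params a [HopfParameters-class] with `lambda > 0`.
#' @param lambdaTarget target excitability (> 0).
#' @return a [HopfParameters-class].
#' @export
rescaledEquivalent <- function(params, lambdaTarget) {
  if (params@lambda <= 0 || lambdaTarget <= 0)
    stop("rescaling requires positive excitability", call. = FALSE)
  HopfParameters(K = params@K * sqrt(lambdaTarget / params@lambda),
                 lambda = lambdaTarget, omega = params@omega, C = params@Cscale,
                 gain = params@gain)
}

#' Rescale an initial condition between excitability levels
#'
#' The amplitude scale of the model at excitability lambda is
#' sqrt(lambda); a state prepared at `lambdaFrom` maps to the matched
#' state at `lambdaTo` by scaling with sqrt(lambdaTo / lambdaFrom).
#'
#' @param ic complex state vector.
#' @param lambdaFrom,lambdaTo source and target excitability (> 0).
#' @return rescaled complex state vector.
#' @export
rescaleInitialCondition <- function(ic, lambdaFrom, lambdaTo) {
  if (lambdaFrom <= 0 || lambdaTo <= 0)
    stop("rescaling requires positive excitability", call. = FALSE)
  ic * sqrt(lambdaTo / lambdaFrom)
}

#' @rdname accessors
setMethod("tsValues", "TimeSeriesPanel", function(x) x@values)
#' @rdname accessors
setMethod("samplingRate", "TimeSeriesPanel", function(x) x@fsHz)
#' @rdname accessors
setMethod("regionLabels", "TimeSeriesPanel", function(x) x@labels)
#' @rdname accessors
setMethod("regionCount", "TimeSeriesPanel", function(x) ncol(x@values))

setMethod("show", "TimeSeriesPanel", function(object) {
  cat("TimeSeriesPanel:", nrow(object@values), "samples x",
      ncol(object@values), "regions at", object@fsHz, "Hz")
  if (length(object@band))
    cat(" (band", object@band[1L], "-", object@band[2L], "Hz)")
  cat("\n")
})

#' Serialize a time-series panel as TSV plus a JSON sidecar
#'
#' @param ts a [TimeSeriesPanel-class].
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param meta optional named list merged into the sidecar (e.g. params,
#'   seed).
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path, meta = list()) {
  m <- ts@values
  colnames(m) <- ts@labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(fsHz = ts@fsHz,
                 band = if (length(ts@band)) ts@band else NULL), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a time-series panel written by [writeTimeSeries]
#'
#' @param path TSV path with a `<path>.json` sidecar.
#' @return a [TimeSeriesPanel-class].
#' @export
readTimeSeries <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("TimeSeriesPanel", values = m, fsHz = as.numeric(side$fsHz),
      labels = colnames(m),
      band = if (!is.null(side$band)) as.numeric(side$band) else numeric(0))
}
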