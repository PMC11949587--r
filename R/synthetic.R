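#' Generate a synthetic connectome
#'
#' Erdos-Renyi topology at the given edge density with log-normal weights
#' (normalized to a maximum of 1), symmetric with zero diagonal, resampled
#' until connected (bounded retries).  Region centroids are sampled
#' uniformly in the unit sphere so spatial clustering is exercised.
#'
#' @param N region count.
#' @param density edge probability in (0, 1].
#' @param seed RNG seed.
#' @param maxTries connectivity resampling bound (default 100).
#' @return a [Connectome-class] whose atlas carries centroids.
#' @export
makeConnectome <- function(N, density = 0.3, seed = 1L, maxTries = 100L) {
  stopIfNot(density > 0 && density <= 1, "density must be in (0, 1]")
  stopIfNot(N >= 2L, "N must be >= 2")
  withSeed(seed, {
    P <- N * (N - 1L) / 2L
    W <- NULL
    for (try in seq_len(maxTries)) {
      edges <- stats::rbinom(P, 1L, density)
      wts <- stats::rlnorm(P, meanlog = 0, sdlog = 0.5) * edges
      M <- matrix(0, N, N)
      M[upper.tri(M)] <- wts
      M <- M + t(M)
      g <- igraph::graph_from_adjacency_matrix(M > 0, mode = "undirected")
      if (igraph::is_connected(g)) {
        W <- M / max(M)
        break
      }
    }
    if (is.null(W))
      stop("failed to sample a connected connectome in ", maxTries,
           " tries (density too low?)", call. = FALSE)
    dirs <- matrix(stats::rnorm(3L * N), N, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cen <- dirs * stats::runif(N)^(1 / 3)
    atlas <- RegionAtlas(sprintf("R%02d", seq_len(N)), cen)
    Connectome(W, atlas)
  })
}

#' Generate alpha-band natural frequencies
#'
#' Peak frequencies drawn uniformly in `bandHz` (default 9-11 Hz, the
#' centre of the alpha analysis band) and converted to angular frequency.
#'
#' @param N region count.
#' @param bandHz c(low, high) in Hz with `low > 4`.
#' @param seed RNG seed.
#' @return numeric vector of angular frequencies omega (rad/s).
#' @export
makeNaturalFrequencies <- function(N, bandHz = c(9, 11), seed = 1L) {
  stopIfNot(length(bandHz) == 2L && bandHz[1L] > 4 &&
              bandHz[2L] >= bandHz[1L], "invalid frequency band")
  withSeed(seed, 2 * pi * stats::runif(N, bandHz[1L], bandHz[2L]))
}

#' Generate a ground-truth "empirical" PLI matrix
#'
#' Simulates `epochs` model runs from distinct initial conditions at the
#' generating parameters, epoch-averages their PLIs, and adds symmetric
#' Gaussian observation noise truncated to [0, 1].  If a tumor mask with
#' gain > 1 is given, the coupling input of the masked regions is
#' multiplied by the gain during simulation (region-wise coupling
#' inflation, the patient pathway).  The generating parameters are
#' attached as attribute `"truth"` so recovery tests can rerun the
#' subject bit-identically.
#'
#' @param W a [Connectome-class].
#' @param omega angular natural frequencies (rad/s).
#' @param KTrue,lambdaTrue generating global parameters.
#' @param epochs number of epochs (>= 1).
#' @param noiseSd observation-noise sd on PLI entries (>= 0).
#' @param seed RNG seed (initial conditions and noise derive from it).
#' @param tumorMask optional [TumorMask-class].
#' @param gain coupling gain on masked regions (>= 1; 1 is neutral).
#' @param settings a [SimulationSettings-class].
#' @param C structural scaling (default 20).
#' @return an empirical-tagged [PLIMatrix-class] with attribute "truth".
#' @export
makeEmpiricalPLI <- function(W, omega, KTrue, lambdaTrue, epochs = 3L,
                             noiseSd = 0.02, seed = 1L, tumorMask = NULL,
                             gain = 1, settings = SimulationSettings(),
                             C = 20) {
  stopIfNot(epochs >= 1L, "epochs must be >= 1")
  N <- regionCount(W)
  g <- rep(1, N)
  if (!is.null(tumorMask) && gain != 1) g[tumorMask@regions] <- gain
  params <- HopfParameters(K = KTrue, lambda = lambdaTrue, omega = omega,
                           C = C, gain = g)
  ics <- sampleInitialConditions(epochs, N, seed)
  plis <- lapply(ics, function(ic) simulatePLI(params, W, ic, settings))
  avg <- epochAveragePLI(plis)@values
  if (noiseSd > 0) {
    avg <- withSeed(seed + 1L, {
      noise <- matrix(0, N, N)
      noise[upper.tri(noise)] <- stats::rnorm(N * (N - 1L) / 2L, 0, noiseSd)
      noise <- noise + t(noise)
      pmin(pmax(avg + noise, 0), 1)
    })
    diag(avg) <- 0
  }
  out <- PLIMatrix(avg, regionLabels(W), source = "empirical")
  attr(out, "truth") <- list(K = KTrue, lambda = lambdaTrue, C = C,
                             gain = gain,
                             maskRegions = if (is.null(tumorMask)) integer(0)
                                           else tumorMask@regions,
                             epochs = as.integer(epochs), noiseSd = noiseSd,
                             seed = as.integer(seed))
  out
}

#' Construct a synthetic cohort specification
#'
#' @param N region count (default 20).
#' @param nControls,nPatients cohort sizes (defaults 33 and 10).
#' @param KControl,KPatient ground-truth coupling per arm (default 8).
#' @param lambdaTrue ground-truth excitability (default 40).
#' @param maskSizeRange c(min, max) tumor-mask size (default c(3, 3)).
#' @param gain tumor coupling gain (default 1.5).
#' @param epochs epochs per subject (default 3).
#' @param noiseSd observation-noise sd (default 0.02).
#' @param density connectome edge density (default 0.3).
#' @param seed master seed.
#' @return a [SyntheticCohortSpec-class].
#' @export
SyntheticCohortSpec <- function(N = 20L, nControls = 33L, nPatients = 10L,
                                KControl = 8, KPatient = 8, lambdaTrue = 40,
                                maskSizeRange = c(3L, 3L), gain = 1.5,
                                epochs = 3L, noiseSd = 0.02, density = 0.3,
                                seed = 1L) {
  new("SyntheticCohortSpec", N = as.integer(N),
      nControls = as.integer(nControls), nPatients = as.integer(nPatients),
      KControl = KControl, KPatient = KPatient, lambdaTrue = lambdaTrue,
      maskSizeRange = as.integer(maskSizeRange), gain = gain,
      epochs = as.integer(epochs), noiseSd = noiseSd, density = density,
      seed = as.integer(seed))
}

#' Generate a synthetic two-cohort study
#'
#' One shared connectome and natural-frequency profile; controls at
#' (KControl, lambdaTrue); patients at (KPatient, lambdaTrue) with the
#' tumor coupling gain applied on a random mask of the specified size.
#' Every per-subject seed derives from the master seed, so the same spec
#' reproduces the same cohort bit-identically.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param settings a [SimulationSettings-class] used for all subjects.
#' @return a [SyntheticCohort-class].
#' @export
makeCohort <- function(spec, settings = SimulationSettings()) {
  validObject(spec)
  conn <- makeConnectome(spec@N, spec@density, seed = spec@seed + 1L)
  omega <- makeNaturalFrequencies(spec@N, seed = spec@seed + 2L)
  subjects <- list()
  for (i in seq_len(spec@nControls)) {
    id <- sprintf("c%02d", i)
    pli <- makeEmpiricalPLI(conn, omega, spec@KControl, spec@lambdaTrue,
                            epochs = spec@epochs, noiseSd = spec@noiseSd,
                            seed = spec@seed + 100L + i, settings = settings)
    subjects[[id]] <- list(id = id, pli = pli, mask = NULL,
                           truth = attr(pli, "truth"))
  }
  for (i in seq_len(spec@nPatients)) {
    id <- sprintf("p%02d", i)
    size <- withSeed(spec@seed + 500L + i,
      sample(spec@maskSizeRange[1L]:spec@maskSizeRange[2L], 1L))
    regions <- withSeed(spec@seed + 600L + i, sample(spec@N, size))
    mask <- TumorMask(id, regions, nRegions = spec@N)
    pli <- makeEmpiricalPLI(conn, omega, spec@KPatient, spec@lambdaTrue,
                            epochs = spec@epochs, noiseSd = spec@noiseSd,
                            seed = spec@seed + 700L + i, tumorMask = mask,
                            gain = spec@gain, settings = settings)
    subjects[[id]] <- list(id = id, pli = pli, mask = mask,
                           truth = attr(pli, "truth"))
  }
  new("SyntheticCohort", connectome = conn, omega = omega,
      subjects = subjects, spec = spec)
}

#' Write a synthetic cohort as a plain-text directory
#'
#' Layout: connectome.csv, atlas.csv, omega.csv, subjects/<id>.csv (PLI
#' matrices with JSON sidecars), masks.json, truth.json.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  writeConnectome(cohort@connectome, file.path(dir, "connectome.csv"))
  writeAtlas(cohort@connectome@atlas, file.path(dir, "atlas.csv"))
  utils::write.csv(data.frame(label = regionLabels(cohort@connectome),
                              omega = cohort@omega),
                   file.path(dir, "omega.csv"), row.names = FALSE)
  masks <- Filter(Negate(is.null),
                  lapply(cohort@subjects, function(s) s$mask))
  writeTumorMasks(masks, cohort@connectome@atlas,
                  file.path(dir, "masks.json"))
  for (s in cohort@subjects)
    writePLI(s$pli, file.path(dir, "subjects", paste0(s$id, ".csv")))
  truth <- lapply(cohort@subjects, function(s) s$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Validate a cohort directory
#'
#' Reads every file written by [writeCohort] back and checks the type
#' invariants (connectome symmetry/nonnegativity, PLI range and symmetry,
#' mask index bounds, omega positivity).
#'
#' @param dir cohort directory.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validateCohortDir <- function(dir) {
  atlas <- readAtlas(file.path(dir, "atlas.csv"))
  conn <- readConnectome(file.path(dir, "connectome.csv"), atlas)
  validObject(conn)
  om <- utils::read.csv(file.path(dir, "omega.csv"))
  stopIfNot(all(om$omega > 0), "omega must be positive")
  stopIfNot(nrow(om) == regionCount(atlas), "omega length mismatch")
  masks <- readTumorMasks(file.path(dir, "masks.json"), atlas)
  for (m in masks) validObject(m)
  files <- list.files(file.path(dir, "subjects"), pattern = "\\.csv$",
                      full.names = TRUE)
  stopIfNot(length(files) > 0L, "no subject PLI files")
  for (f in files) validObject(readPLI(f, atlas))
  invisible(TRUE)
}

setMethod("show", "SyntheticCohort", function(object) {
  nP <- sum(!vapply(object@subjects, function(s) is.null(s$mask), logical(1)))
  cat("SyntheticCohort:", length(object@subjects) - nP, "controls,", nP,
      "patients,", object@spec@N, "regions (seed", object@spec@seed, ")\n")
})
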