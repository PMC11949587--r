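#' Construct a PLI matrix
#'
#' @param values symmetric N x N matrix in [0, 1] with zero diagonal.
#' @param labels region labels.
#' @param source "simulated" or "empirical".
#' @param threshold thresholding provenance: `list()` if none, else
#'   `list(kind = "percentile"|"median", level = ...)`.
#' @return a [PLIMatrix-class].
#' @export
PLIMatrix <- function(values, labels, source = "simulated",
                      threshold = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(labels, labels)
  new("PLIMatrix", values = values, labels = as.character(labels),
      source = source, threshold = threshold)
}

#' Phase-lag index of a phase panel
#'
#' PLI_ij = | mean_t sign( sin( phi_i(t) - phi_j(t) ) ) |, with sign(0)
#' contributing 0, so identical signals give PLI 0 (full symmetry of the
#' phase-difference distribution) and a consistent lead/lag gives PLI 1.
#'
#' @param phases a [PhasePanel-class] (or plain T x N phase matrix) with
#'   at least 2 samples.
#' @param source source tag for the result (default "simulated").
#' @return a [PLIMatrix-class].
#' @export
phaseLagIndex <- function(phases, source = "simulated") {
  if (is(phases, "PhasePanel")) {
    m <- phases@phases
    labels <- phases@labels
  } else {
    m <- as.matrix(phases)
    labels <- colnames(m) %||% sprintf("R%02d", seq_len(ncol(m)))
  }
  stopIfNot(nrow(m) >= 2L, "need at least 2 samples")
  N <- ncol(m)
  res <- .C("pli_signmean", as.double(m), as.integer(nrow(m)),
            as.integer(N), out = double(N * N), PACKAGE = "hopfconn")
  PLIMatrix(matrix(res$out, N, N), labels, source = source)
}

#' Average PLI matrices over epochs
#'
#' Entrywise arithmetic mean of unthresholded PLI matrices with matching
#' labels (the subject-level PLI is the mean over that subject's epochs).
#'
#' @param plis nonempty list of [PLIMatrix-class] objects.
#' @return a [PLIMatrix-class].
#' @export
epochAveragePLI <- function(plis) {
  stopIfNot(length(plis) > 0L, "need at least one PLI matrix")
  labels <- plis[[1L]]@labels
  src <- plis[[1L]]@source
  for (p in plis) {
    if (!identical(p@labels, labels))
      stop("PLI matrices have mismatched labels", call. = FALSE)
    if (isThresholded(p))
      stop("cannot epoch-average thresholded PLI matrices", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(plis, function(p) p@values)) / length(plis)
  PLIMatrix(avg, labels, source = src)
}

#' Percentile-threshold a PLI matrix
#'
#' Sets the lowest `percent`% of off-diagonal (upper-triangle) entries to
#' zero as ordered per magnitude, mirroring to the lower triangle.  Of the
#' P = N(N-1)/2 pairs, exactly `floor(P * percent / 100)` are zeroed; ties
#' are broken by the stable pair ordering (magnitude, then column-major
#' pair position), so the count is deterministic.
#'
#' @param pli an unthresholded [PLIMatrix-class].
#' @param percent percentage in [0, 100).
#' @return a thresholded [PLIMatrix-class] with provenance recorded.
#' @export
thresholdPLI <- function(pli, percent) {
  stopIfNot(!isThresholded(pli), "PLI is already thresholded")
  if (percent >= 100)
    stop("thresholding at 100% leaves an all-zero matrix (undefined objective)",
         call. = FALSE)
  stopIfNot(percent >= 0, "percent must be in [0, 100)")
  n <- length(pli@labels)
  pairs <- upperPairs(n)
  vals <- pli@values[pairs]
  nZero <- floor(nrow(pairs) * percent / 100)
  out <- pli@values
  if (nZero > 0L) {
    ord <- order(abs(vals))  # stable: ties keep pair order (col-major)
    kill <- pairs[ord[seq_len(nZero)], , drop = FALSE]
    out[kill] <- 0
    out[kill[, c(2L, 1L), drop = FALSE]] <- 0
  }
  PLIMatrix(out, pli@labels, source = pli@source,
            threshold = list(kind = "percentile", level = percent))
}

#' Median-threshold a PLI matrix
#'
#' Sets all off-diagonal entries strictly below the median of the
#' off-diagonal (upper-triangle) entries to zero.
#'
#' @param pli an unthresholded [PLIMatrix-class].
#' @return a thresholded [PLIMatrix-class].
#' @export
medianThresholdPLI <- function(pli) {
  stopIfNot(!isThresholded(pli), "PLI is already thresholded")
  med <- stats::median(upperTriValues(pli@values))
  out <- pli@values
  out[out < med] <- 0
  diag(out) <- 0
  PLIMatrix(out, pli@labels, source = pli@source,
            threshold = list(kind = "median", level = med))
}

#' Read a PLI matrix from labeled CSV
#'
#' A JSON sidecar `<path>.json` (as written by [writePLI]) restores the
#' source tag and threshold provenance when present.
#'
#' @param path CSV path (header row of region labels).
#' @param atlas optional [RegionAtlas-class] to validate label order.
#' @return a [PLIMatrix-class].
#' @export
readPLI <- function(path, atlas = NULL) {
  m <- readLabeledMatrix(path)
  if (!is.null(atlas) && !identical(colnames(m), regionLabels(atlas)))
    stop("PLI labels do not match the atlas order", call. = FALSE)
  side <- paste0(path, ".json")
  src <- "empirical"
  thr <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    src <- meta$source %||% src
    if (!is.null(meta$threshold) && length(meta$threshold))
      thr <- as.list(meta$threshold)
  }
  PLIMatrix(m, colnames(m), source = src, threshold = thr)
}

#' Write a PLI matrix to labeled CSV with a JSON sidecar
#'
#' @param pli a [PLIMatrix-class].
#' @param path output CSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writePLI <- function(pli, path) {
  writeLabeledMatrix(pli@values, path)
  jsonlite::write_json(list(source = pli@source, threshold = pli@threshold),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname accessors
setMethod("pliValues", "PLIMatrix", function(x) x@values)
#' @rdname accessors
setMethod("pliSource", "PLIMatrix", function(x) x@source)
#' @rdname accessors
setMethod("pliThreshold", "PLIMatrix", function(x) x@threshold)
#' @rdname accessors
setMethod("isThresholded", "PLIMatrix", function(x) length(x@threshold) > 0L)
#' @rdname accessors
setMethod("regionLabels", "PLIMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("regionCount", "PLIMatrix", function(x) length(x@labels))

setMethod("show", "PLIMatrix", function(object) {
  ut <- upperTriValues(object@values)
  cat("PLIMatrix (", object@source, "): ", length(object@labels),
      " regions, mean PLI ", signif(mean(ut), 3), sep = "")
  if (isThresholded(object))
    cat(", thresholded (", object@threshold$kind, " ",
        signif(object@threshold$level, 3), ")", sep = "")
  cat("\n")
})
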