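#' Construct a connectome
#'
#' Validates and wraps an N x N nonnegative symmetric weight matrix.
#' Asymmetric input within tolerance of use cases like streamline-count
#' matrices is handled by [readConnectome]; this constructor requires a
#' valid matrix.
#'
#' @param W numeric N x N weight matrix.
#' @param atlas the [RegionAtlas-class] defining region order.
#' @return a [Connectome-class].
#' @export
Connectome <- function(W, atlas) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  dimnames(W) <- list(atlas@labels, atlas@labels)
  new("Connectome", W = W, atlas = atlas)
}

#' Read a connectome matrix from a delimited file
#'
#' The file must be CSV/TSV with a header row of region labels matching
#' the atlas order.  Input that is asymmetric within numerical tolerance
#' (as streamline-count matrices from tractography tools typically are) is
#' symmetrized by averaging `(W + t(W))/2` with a warning; a nonzero
#' diagonal is forced to zero with a warning.  Negative weights and
#' dimension mismatches are errors.
#'
#' @param path file path (delimiter inferred from the extension: `.tsv`
#'   reads tab-separated, anything else comma-separated).
#' @param atlas the [RegionAtlas-class] the matrix must match.
#' @return a validated [Connectome-class].
#' @export
readConnectome <- function(path, atlas) {
  W <- readLabeledMatrix(path)
  n <- regionCount(atlas)
  if (nrow(W) != n || ncol(W) != n)
    stop("connectome dimensions (", nrow(W), "x", ncol(W),
         ") do not match the atlas (", n, " regions)", call. = FALSE)
  if (!identical(colnames(W), atlas@labels))
    stop("connectome header labels do not match the atlas order", call. = FALSE)
  if (any(W < 0)) stop("negative connectome weight", call. = FALSE)
  asym <- max(abs(W - t(W)))
  if (asym > 0) {
    if (asym > 0.5 * max(abs(W)))
      stop("connectome is grossly asymmetric (max |W - t(W)| = ", asym, ")",
           call. = FALSE)
    warning("asymmetric connectome symmetrized by averaging (max deviation ",
            signif(asym, 3), ")", call. = FALSE)
    W <- (W + t(W)) / 2
  }
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal forced to zero", call. = FALSE)
    diag(W) <- 0
  }
  Connectome(W, atlas)
}

#' Write a connectome to a delimited file
#'
#' @param x a [Connectome-class].
#' @param path output path (`.tsv` writes tab-separated, else CSV).
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(x, path) {
  writeLabeledMatrix(x@W, path)
  invisible(path)
}

readLabeledMatrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- colnames(m)
  m
}

writeLabeledMatrix <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # %.17g keeps doubles bit-exact through the write/read round trip
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  utils::write.table(rbind(colnames(m), chr), path, sep = sep,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname accessors
setMethod("regionCount", "Connectome", function(x) nrow(x@W))
#' @rdname accessors
setMethod("regionLabels", "Connectome", function(x) x@atlas@labels)
#' @rdname accessors
setMethod("connWeights", "Connectome", function(x) x@W)
#' @rdname accessors
setMethod("atlasCentroids", "Connectome", function(x) atlasCentroids(x@atlas))

setMethod("show", "Connectome", function(object) {
  W <- object@W
  cat("Connectome:", nrow(W), "regions,",
      sum(upperTriValues(W) > 0), "of", choose(nrow(W), 2), "edges positive\n")
  cat("  weight range: [", signif(min(W), 3), ",", signif(max(W), 3), "]\n")
})
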