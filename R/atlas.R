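#' Construct a region atlas
#'
#' @param labels character vector of unique region names (length >= 2).
#' @param centroids optional N x 3 matrix of centroid coordinates in mm.
#' @return a [RegionAtlas-class].
#' @examples
#' RegionAtlas(c("A", "B", "C"))
#' @export
RegionAtlas <- function(labels, centroids = NULL) {
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0L, 3L)
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  new("RegionAtlas", labels = as.character(labels), centroids = centroids)
}

#' Read a region atlas from CSV
#'
#' Expects a header `label[,x,y,z]`; the x/y/z centroid columns are
#' optional.  Region order in the file defines the canonical order.
#'
#' @param path CSV file path.
#' @return a [RegionAtlas-class].
#' @export
readAtlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot("label" %in% names(df), "atlas CSV needs a 'label' column")
  cen <- NULL
  if (all(c("x", "y", "z") %in% names(df)))
    cen <- as.matrix(df[, c("x", "y", "z")])
  RegionAtlas(df$label, cen)
}

#' Write a region atlas to CSV
#'
#' @param atlas a [RegionAtlas-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  df <- data.frame(label = atlas@labels, stringsAsFactors = FALSE)
  if (hasCentroids(atlas)) {
    df$x <- atlas@centroids[, 1L]
    df$y <- atlas@centroids[, 2L]
    df$z <- atlas@centroids[, 3L]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Does an atlas carry centroid coordinates?
#' @param atlas a [RegionAtlas-class].
#' @return logical.
#' @export
hasCentroids <- function(atlas) nrow(atlas@centroids) > 0L

#' Accessors for hopfconn data classes
#'
#' `regionCount` and `regionLabels` apply to atlases, connectomes, PLI
#' matrices, and signal/phase panels; the remaining accessors retrieve the
#' obvious slot of their class.
#'
#' @param x an object of the documented classes.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("regionCount", "RegionAtlas", function(x) length(x@labels))
#' @rdname accessors
setMethod("regionLabels", "RegionAtlas", function(x) x@labels)
#' @rdname accessors
setMethod("atlasCentroids", "RegionAtlas", function(x) {
  if (!hasCentroids(x)) stop("atlas has no centroids", call. = FALSE)
  x@centroids
})

setMethod("show", "RegionAtlas", function(object) {
  cat("RegionAtlas with", length(object@labels), "regions",
      if (hasCentroids(object)) "(with centroids)" else "(no centroids)", "\n")
  cat("  labels:", paste(utils::head(object@labels, 5L), collapse = ", "),
      if (length(object@labels) > 5L) "..." else "", "\n")
})
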