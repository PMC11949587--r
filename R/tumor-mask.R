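#' Construct a tumor mask
#'
#' @param subjectId subject identifier.
#' @param regions integer vector of region indices (1-based) or character
#'   vector of region labels (requires `atlas`).
#' @param nRegions atlas region count (ignored when `atlas` is given).
#' @param atlas optional [RegionAtlas-class] used to resolve labels.
#' @return a [TumorMask-class].
#' @export
TumorMask <- function(subjectId, regions, nRegions = NULL, atlas = NULL) {
  if (!is.null(atlas)) {
    nRegions <- regionCount(atlas)
    if (is.character(regions)) {
      idx <- match(regions, regionLabels(atlas))
      if (anyNA(idx))
        stop("unknown region labels: ",
             paste(regions[is.na(idx)], collapse = ", "), call. = FALSE)
      regions <- idx
    }
  }
  stopIfNot(!is.null(nRegions), "nRegions (or atlas) is required")
  new("TumorMask", subjectId = as.character(subjectId),
      regions = sort(unique(as.integer(regions))),
      nRegions = as.integer(nRegions))
}

#' Read tumor masks from JSON
#'
#' The file maps subject id to a list of region labels, e.g.
#' `{"p01": ["R03", "R07"]}`.
#'
#' @param path JSON file path.
#' @param atlas the [RegionAtlas-class] used to resolve labels.
#' @return named list of [TumorMask-class] objects.
#' @export
readTumorMasks <- function(path, atlas) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- lapply(names(raw), function(id)
    TumorMask(id, as.character(raw[[id]]), atlas = atlas))
  names(masks) <- names(raw)
  masks
}

#' Write tumor masks to JSON
#'
#' @param masks list of [TumorMask-class] objects.
#' @param atlas the [RegionAtlas-class] supplying labels.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTumorMasks <- function(masks, atlas, path) {
  out <- lapply(masks, function(m) regionLabels(atlas)[m@regions])
  names(out) <- vapply(masks, function(m) m@subjectId, character(1))
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Union of tumor masks
#'
#' Set-union of the region indices of several masks referring to the same
#' atlas (the pooled "union of all tumor regions" used in cluster-level
#' analyses).
#'
#' @param masks nonempty list of [TumorMask-class] objects.
#' @param subjectId id for the union mask (default "union").
#' @return a [TumorMask-class].
#' @export
unionTumorRegions <- function(masks, subjectId = "union") {
  stopIfNot(length(masks) > 0L, "need at least one mask")
  n <- unique(vapply(masks, function(m) m@nRegions, integer(1)))
  stopIfNot(length(n) == 1L, "masks refer to different atlases")
  TumorMask(subjectId,
            sort(unique(unlist(lapply(masks, function(m) m@regions)))),
            nRegions = n)
}

#' Spatially cluster tumor regions
#'
#' K-means on the 3-D centroids of the union of the tumor regions, with a
#' fixed seed and multiple restarts (lowest within-cluster sum of squares
#' kept), so cluster assignment is deterministic given the seed.
#'
#' @param masks list of [TumorMask-class] objects.
#' @param atlas a [RegionAtlas-class] with centroids.
#' @param nClusters number of clusters (default 3).
#' @param seed RNG seed for the restarts.
#' @param nStart number of random restarts (default 100).
#' @return named integer vector mapping region index to cluster id, with
#'   the within-cluster sum of squares in attribute `"withinss"`.
#' @export
clusterTumorRegions <- function(masks, atlas, nClusters = 3L, seed = 1L,
                                nStart = 100L) {
  if (!hasCentroids(atlas))
    stop("atlas has no centroids; spatial clustering unavailable", call. = FALSE)
  u <- unionTumorRegions(masks)
  stopIfNot(u@nRegions == regionCount(atlas), "masks do not match the atlas")
  idx <- u@regions
  if (nClusters > length(idx))
    stop("nClusters (", nClusters, ") exceeds the ", length(idx),
         " distinct tumor regions", call. = FALSE)
  pts <- atlas@centroids[idx, , drop = FALSE]
  km <- withSeed(seed,
    stats::kmeans(pts, centers = nClusters, nstart = nStart, iter.max = 100L))
  out <- structure(as.integer(km$cluster), names = as.character(idx))
  attr(out, "withinss") <- sum(km$withinss)
  out
}

#' @rdname accessors
setMethod("maskRegions", "TumorMask", function(x) x@regions)

setMethod("show", "TumorMask", function(object) {
  cat("TumorMask '", object@subjectId, "': ", length(object@regions),
      " of ", object@nRegions, " regions\n", sep = "")
})
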