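#' @import methods
#' @include AllGenerics.R
NULL

.checkGrid <- function(dims, voxelSize) {
  msgs <- character(0)
  if (length(dims) != 3L)
    msgs <- c(msgs, "volumes must be 3-D (nx, ny, nz)")
  if (length(dims) == 3L && dims[1L] %% 2L != 0L)
    msgs <- c(msgs, paste(
      "the left-right dimension (nx) must be even so that the",
      "mid-sagittal plane falls between the two central voxel columns",
      "and left-right flipping is an exact involution"))
  if (length(voxelSize) != 3L)
    msgs <- c(msgs, "'voxelSize' must have length 3 (mm per axis)")
  if (any(!is.finite(voxelSize)) || any(voxelSize <= 0))
    msgs <- c(msgs, "all voxel sizes must be finite and > 0 (mm)")
  msgs
}

#' Brain volume classes
#'
#' S4 containers for registered 3-D brain volumes on a shared voxel grid.
#' The axis convention is fixed: axis 1 runs left to right, axis 2 posterior
#' to anterior, axis 3 inferior to superior. The left-right dimension must
#' have an even number of voxels so the mid-sagittal plane lies exactly
#' between the two central columns; [flipLR()] is then an exact involution
#' and hemisphere membership is unambiguous.
#'
#' `ScalarVolume` holds real-valued data (e.g. standardized PET activation),
#' `BrainMask` holds logical data (brain masks, tracings, cluster and atlas
#' object maps), and `TissueLabels` holds integer tissue codes
#' (0 = background, 1 = grey matter, 2 = white matter, 3 = CSF; see
#' [tissueCodes()]).
#'
#' @slot voxels 3-D array of voxel values.
#' @slot voxelSize numeric(3), voxel edge lengths in mm, all > 0.
#'
#' @aliases ScalarVolume-class BrainMask-class TissueLabels-class
#'   BrainVolume-class
#' @name BrainVolume
NULL

setClass("BrainVolume", representation("VIRTUAL",
  voxels = "array",
  voxelSize = "numeric"
))

setValidity("BrainVolume", function(object) {
  msgs <- .checkGrid(dim(object@voxels), object@voxelSize)
  if (length(msgs)) msgs else TRUE
})

#' @rdname BrainVolume
#' @exportClass ScalarVolume
setClass("ScalarVolume", contains = "BrainVolume")

setValidity("ScalarVolume", function(object) {
  if (!is.numeric(object@voxels))
    "ScalarVolume voxels must be numeric" else TRUE
})

#' @rdname BrainVolume
#' @exportClass BrainMask
setClass("BrainMask", contains = "BrainVolume")

setValidity("BrainMask", function(object) {
  if (!is.logical(object@voxels))
    "BrainMask voxels must be logical" else TRUE
})

#' @rdname BrainVolume
#' @exportClass TissueLabels
setClass("TissueLabels", contains = "BrainVolume")

setValidity("TissueLabels", function(object) {
  v <- object@voxels
  if (!is.integer(v))
    return("TissueLabels voxels must be integer")
  if (!all(v %in% 0:3))
    return("tissue labels restricted to 0 (background), 1 (GM), 2 (WM), 3 (CSF)")
  TRUE
})

#' @param values 3-D array of voxel values (numeric for `ScalarVolume`,
#'   coercible to logical for `BrainMask`, integer codes in 0..3 for
#'   `TissueLabels`).
#' @param voxelSize numeric(3), voxel edge lengths in mm.
#' @return A `ScalarVolume`, `BrainMask` or `TissueLabels` object.
#' @examples
#' v <- ScalarVolume(array(rnorm(64), dim = c(4, 4, 4)), c(2, 2, 2))
#' gridDim(v)
#' voxelVolume(v)  # 8 mm^3
#' @rdname BrainVolume
#' @export
ScalarVolume <- function(values, voxelSize) {
  storage.mode(values) <- "double"
  new("ScalarVolume", voxels = values, voxelSize = as.numeric(voxelSize))
}

#' @rdname BrainVolume
#' @export
BrainMask <- function(values, voxelSize) {
  if (!is.logical(values)) {
    values <- array(as.numeric(values) != 0, dim = dim(values))
  }
  new("BrainMask", voxels = values, voxelSize = as.numeric(voxelSize))
}

#' @rdname BrainVolume
#' @export
TissueLabels <- function(values, voxelSize) {
  storage.mode(values) <- "integer"
  new("TissueLabels", voxels = values, voxelSize = as.numeric(voxelSize))
}

#' Tissue label codes
#'
#' Integer codes used by [TissueLabels] volumes.
#'
#' @return Named integer vector: background = 0, gm = 1, wm = 2, csf = 3.
#' @export
tissueCodes <- function() {
  c(background = 0L, gm = 1L, wm = 2L, csf = 3L)
}

#' @rdname volumeAccessors
#' @export
setMethod("voxels", "BrainVolume", function(x) x@voxels)

#' Volume accessors
#'
#' @param x a volume object.
#' @return `voxels()` the voxel array; `voxelSize()` mm per axis;
#'   `gridDim()` integer grid dimensions; `voxelVolume()` the volume of a
#'   single voxel in mm^3.
#' @name volumeAccessors
NULL

#' @rdname volumeAccessors
#' @export
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)

#' @rdname volumeAccessors
#' @export
setMethod("gridDim", "BrainVolume", function(x) dim(x@voxels))

#' @rdname volumeAccessors
#' @export
setMethod("voxelVolume", "BrainVolume", function(x) prod(x@voxelSize))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@voxels)
  cat(class(object), sprintf("%d x %d x %d voxels", d[1], d[2], d[3]),
      sprintf("(%.3g x %.3g x %.3g mm)\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  if (is(object, "BrainMask")) {
    cat("  in-mask voxels:", sum(object@voxels), "\n")
  } else if (is(object, "TissueLabels")) {
    tb <- tabulate(object@voxels + 1L, nbins = 4L)
    cat(sprintf("  background %d | GM %d | WM %d | CSF %d\n",
                tb[1], tb[2], tb[3], tb[4]))
  } else {
    cat(sprintf("  value range [%.4g, %.4g]\n",
                min(object@voxels), max(object@voxels)))
  }
  invisible(NULL)
})

.sameGrid <- function(a, b) {
  identical(dim(a@voxels), dim(b@voxels)) &&
    isTRUE(all.equal(a@voxelSize, b@voxelSize))
}

.stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!.sameGrid(a, b))
    stop(what, " must share one grid (same dimensions and voxel size)",
         call. = FALSE)
  invisible(TRUE)
}

#' Voxelwise group t-map
#'
#' One-sample t statistics of aligned per-subject difference volumes
#' against zero, computed voxel by voxel. Degrees of freedom are
#' `nSubjects - 1`. Voxels where the between-subject standard deviation is
#' zero are assigned t = 0 and flagged in `zeroSD`.
#'
#' @slot tvals 3-D array of t values.
#' @slot voxelSize numeric(3) mm.
#' @slot df integer degrees of freedom.
#' @slot nSubjects integer number of subjects.
#' @slot zeroSD logical array flagging degenerate (sd = 0) voxels.
#' @seealso [groupTMap()], [extractClusters()]
#' @exportClass TMap
setClass("TMap", representation(
  tvals = "array",
  voxelSize = "numeric",
  df = "integer",
  nSubjects = "integer",
  zeroSD = "array"
))

setValidity("TMap", function(object) {
  msgs <- .checkGrid(dim(object@tvals), object@voxelSize)
  if (object@df != object@nSubjects - 1L)
    msgs <- c(msgs, "df must equal nSubjects - 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TMap", function(object) {
  d <- dim(object@tvals)
  cat(sprintf("TMap %d x %d x %d, n = %d subjects, df = %d\n",
              d[1], d[2], d[3], object@nSubjects, object@df))
  cat(sprintf("  t range [%.3f, %.3f]; %d zero-sd voxels\n",
              min(object@tvals), max(object@tvals), sum(object@zeroSD)))
  invisible(NULL)
})

#' @rdname volumeAccessors
#' @export
setMethod("voxelSize", "TMap", function(x) x@voxelSize)

#' @rdname volumeAccessors
#' @export
setMethod("gridDim", "TMap", function(x) dim(x@tvals))

#' @rdname volumeAccessors
#' @export
setMethod("voxelVolume", "TMap", function(x) prod(x@voxelSize))

#' Supra-threshold cluster set
#'
#' Connected components of a thresholded t-map that survive the minimum
#' extent rule, with per-cluster peak statistics and reported millimetre
#' coordinates. `clusterTable()` returns the summary data frame (one row
#' per cluster, sorted by peak t descending); `clusterVoxels()` the list of
#' voxel index matrices.
#'
#' @slot table data.frame with columns `cluster`, `peak_t`, `x`, `y`, `z`,
#'   `volume_mm3`, `n_voxels`, `hemisphere`.
#' @slot voxels list of integer matrices (one row per voxel: i, j, k).
#' @slot tThreshold numeric t threshold applied.
#' @slot minExtentMM3 numeric minimum cluster extent in mm^3.
#' @slot connectivity integer neighborhood (6, 18 or 26).
#' @exportClass ClusterSet
setClass("ClusterSet", representation(
  table = "data.frame",
  voxels = "list",
  tThreshold = "numeric",
  minExtentMM3 = "numeric",
  connectivity = "integer"
))

#' @describeIn ClusterSet summary table, one row per retained cluster.
#' @param x,object a `ClusterSet`.
#' @export
clusterTable <- function(x) x@table

#' @describeIn ClusterSet list of n-by-3 voxel index matrices.
#' @export
clusterVoxels <- function(x) x@voxels

#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@table))

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf(
    "ClusterSet: %d cluster(s) at t >= %.3f, extent >= %.0f mm^3, %d-connectivity\n",
    nrow(object@table), object@tThreshold, object@minExtentMM3,
    object@connectivity))
  if (nrow(object@table)) print(object@table, row.names = FALSE)
  invisible(NULL)
})

#' Probabilistic overlap atlas
#'
#' Voxelwise count of how many subjects' binary tracings contain each voxel
#' (0 to `nSubjects`). Thresholding the counts at a fractional overlap
#' level yields per-hemisphere object maps; see [thresholdAtlas()].
#'
#' @slot counts integer 3-D array of overlap counts.
#' @slot voxelSize numeric(3) mm.
#' @slot nSubjects integer number of tracings summed.
#' @seealso [sumTracings()], [minOverlapCount()], [atlasVolume()]
#' @exportClass OverlapAtlas
setClass("OverlapAtlas", representation(
  counts = "array",
  voxelSize = "numeric",
  nSubjects = "integer"
))

setValidity("OverlapAtlas", function(object) {
  msgs <- .checkGrid(dim(object@counts), object@voxelSize)
  if (any(object@counts < 0L) || any(object@counts > object@nSubjects))
    msgs <- c(msgs, "counts must lie in [0, nSubjects]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OverlapAtlas", function(object) {
  d <- dim(object@counts)
  cat(sprintf("OverlapAtlas %d x %d x %d, n = %d subjects, max overlap %d\n",
              d[1], d[2], d[3], object@nSubjects, max(object@counts)))
  invisible(NULL)
})

#' @describeIn OverlapAtlas the integer count array.
#' @param x,object an `OverlapAtlas`.
#' @export
overlapCounts <- function(x) x@counts

#' @describeIn OverlapAtlas number of subjects summed into the atlas.
#' @export
nAtlasSubjects <- function(x) x@nSubjects

#' @rdname volumeAccessors
#' @export
setMethod("voxelSize", "OverlapAtlas", function(x) x@voxelSize)

#' @rdname volumeAccessors
#' @export
setMethod("gridDim", "OverlapAtlas", function(x) dim(x@counts))

#' @rdname volumeAccessors
#' @export
setMethod("voxelVolume", "OverlapAtlas", function(x) prod(x@voxelSize))
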