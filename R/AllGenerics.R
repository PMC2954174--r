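NULL

#' Flip a volume across the mid-sagittal plane
#'
#' Reverses the left-right (first) axis of a volume. Because the grid is
#' required to have an even number of columns, the mid-sagittal plane falls
#' exactly between the two central voxel columns and flipping is an exact
#' involution: `flipLR(flipLR(x))` is identical to `x`.
#'
#' @param x a [ScalarVolume], [BrainMask] or [TissueLabels] object.
#' @return An object of the same class with voxel `(i, j, k)` moved to
#'   `(nx - i + 1, j, k)`; the grid geometry is unchanged.
#' @examples
#' v <- ScalarVolume(array(1:8, dim = c(2, 2, 2)), voxelSize = c(1, 1, 1))
#' identical(voxels(flipLR(flipLR(v))), voxels(v))
#' @export
setGeneric("flipLR", function(x) standardGeneric("flipLR"))

#' @rdname volumeAccessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname volumeAccessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volumeAccessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname volumeAccessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
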