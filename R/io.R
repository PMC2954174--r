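#' @include AllClasses.R
NULL

#' Read and write NIfTI-1 volumes
#'
#' `readVolume()` loads a 3-D NIfTI-1 file into a [ScalarVolume],
#' [BrainMask] or [TissueLabels] object; `writeVolume()` writes one back.
#' Values and voxel sizes round-trip exactly (scalar volumes are stored as
#' float64, masks and label volumes as uint8). Files whose header carries a
#' complete orientation are reoriented at load to the package convention
#' (axis 1 left to right, axis 2 posterior to anterior, axis 3 inferior to
#' superior). Label volumes are accompanied by a JSON sidecar naming the
#' tissue codes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param type one of `"scalar"`, `"mask"`, `"labels"`; for `"mask"` any
#'   nonzero voxel is TRUE, for `"labels"` values must be integer codes in
#'   0..3.
#' @return `readVolume()` returns a volume object of the requested type;
#'   `writeVolume()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' v <- ScalarVolume(array(rnorm(512), dim = c(8, 8, 8)), c(0.6, 0.6, 0.6))
#' writeVolume(v, f)
#' v2 <- readVolume(f)
#' all.equal(voxels(v), voxels(v2))
#' @export
readVolume <- function(path, type = c("scalar", "mask", "labels")) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)),
         "-D data in ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-finite or non-positive voxel size in ", path, call. = FALSE)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nzchar(orient) && orient != "RAS") {
    RNifti::orientation(img) <- "RAS"
    pd <- RNifti::pixdim(img)[1:3]
  }
  a <- array(as.numeric(img), dim = dim(img))
  switch(type,
    scalar = ScalarVolume(a, pd),
    mask = BrainMask(a, pd),
    labels = TissueLabels(array(as.integer(round(a)), dim = dim(a)), pd)
  )
}

#' @param v the volume object to write.
#' @rdname readVolume
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "BrainVolume"))
  a <- v@voxels
  if (is(v, "ScalarVolume")) {
    dtype <- "double"
  } else {
    dtype <- "uint8"
    a <- array(as.integer(a), dim = dim(a))
  }
  attr(a, "pixdim") <- v@voxelSize
  img <- RNifti::asNifti(a, datatype = dtype)
  RNifti::writeNifti(img, path, datatype = dtype)
  if (is(v, "TissueLabels")) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(as.list(tissueCodes()), sidecar, auto_unbox = TRUE)
  }
  invisible(path)
}
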