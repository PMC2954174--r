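#' @include AllClasses.R volume-ops.R
NULL

#' Sum per-subject tracings into an overlap atlas
#'
#' Counts, for every voxel, how many subjects' binary tracings contain it.
#' Subjects whose tracing is empty in either hemisphere are excluded with
#' a warning (an unreliable tracing cannot contribute to a bilateral
#' atlas); `nSubjects` reflects the retained subjects.
#'
#' @param tracings list of bilateral tracing [BrainMask]s on one grid.
#' @return An [OverlapAtlas].
#' @export
sumTracings <- function(tracings) {
  if (!is.list(tracings) || length(tracings) < 1L)
    stop("need at least one tracing", call. = FALSE)
  stopifnot(all(vapply(tracings, is, logical(1), "BrainMask")))
  for (i in seq_along(tracings)[-1L])
    .stopIfGridMismatch(tracings[[1L]], tracings[[i]], "tracings")
  hemi <- hemisphereMasks(tracings[[1L]])
  ok <- vapply(tracings, function(tr) {
    any(tr@voxels & hemi$left@voxels) && any(tr@voxels & hemi$right@voxels)
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " tracing(s) empty in one hemisphere excluded from ",
            "the atlas", call. = FALSE)
  kept <- tracings[ok]
  if (!length(kept))
    stop("no tracing is nonempty in both hemispheres", call. = FALSE)
  counts <- Reduce(`+`, lapply(kept, function(tr)
    array(as.integer(tr@voxels), dim = dim(tr@voxels))))
  new("OverlapAtlas", counts = counts,
      voxelSize = tracings[[1L]]@voxelSize, nSubjects = length(kept))
}

#' Minimum overlap count for a fractional threshold
#'
#' The smallest number of subjects a voxel must appear in to survive a
#' fractional overlap threshold: the nearest integer to `fraction * n`
#' (halves round up), never below 1. With n = 62 this maps the 30%, 50%
#' and 70% criterion levels to 19, 31 and 43 subjects.
#'
#' @param n number of subjects in the atlas.
#' @param fraction overlap fraction in (0, 1).
#' @return Integer minimum subject count.
#' @examples
#' minOverlapCount(62, 0.30)  # 19
#' minOverlapCount(62, 0.70)  # 43
#' @export
minOverlapCount <- function(n, fraction) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be >= 1", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  max(1L, as.integer(floor(fraction * n + 0.5)))
}

#' Threshold an overlap atlas into per-hemisphere object maps
#'
#' Keeps voxels present in at least [minOverlapCount()] subjects and
#' splits the surviving object map at the mid-sagittal plane. Raising the
#' fraction can only shrink the maps (level sets of the count volume are
#' nested).
#'
#' @param atlas an [OverlapAtlas].
#' @param fraction overlap fraction in (0, 1).
#' @return List with [BrainMask] elements `left` and `right`.
#' @export
thresholdAtlas <- function(atlas, fraction) {
  stopifnot(is(atlas, "OverlapAtlas"))
  k <- minOverlapCount(atlas@nSubjects, fraction)
  obj <- atlas@counts >= k
  if (!any(obj))
    warning("object map empty at fraction ", fraction,
            " (requires >= ", k, " subjects)", call. = FALSE)
  hemi <- hemisphereMasks(atlas)
  list(left = BrainMask(obj & hemi$left@voxels, atlas@voxelSize),
       right = BrainMask(obj & hemi$right@voxels, atlas@voxelSize))
}

#' Physical volume of a mask
#'
#' @param mask a [BrainMask].
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
atlasVolume <- function(mask) {
  stopifnot(is(mask, "BrainMask"))
  sum(mask@voxels) * voxelVolume(mask)
}

#' Tabulate object-map volumes across thresholds
#'
#' @param atlas an [OverlapAtlas].
#' @param fractions numeric vector of overlap fractions.
#' @return data.frame with columns `fraction`, `hemisphere`, `mm3`.
#' @export
atlasVolumeTable <- function(atlas, fractions = c(0.3, 0.5, 0.7)) {
  do.call(rbind, lapply(fractions, function(f) {
    maps <- thresholdAtlas(atlas, f)
    data.frame(fraction = f, hemisphere = c("left", "right"),
               mm3 = c(atlasVolume(maps$left), atlasVolume(maps$right)),
               stringsAsFactors = FALSE)
  }))
}
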