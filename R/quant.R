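#' @include AllClasses.R volume-ops.R
NULL

#' Tissue percentages inside an object map
#'
#' Percentage of grey matter, white matter and CSF voxels among all voxels
#' of a binary map, each computed against the full map volume. With no
#' CSF or unlabeled voxels in the map, `pct_gm + pct_wm = 100` exactly, so
#' GM and WM percentages are perfectly anticorrelated across subjects.
#'
#' @param map a [BrainMask] object map (hemisphere atlas map or VOI).
#' @param seg a [TissueLabels] segmentation on the same grid.
#' @param label optional label used in the error message when the map is
#'   empty (e.g. `"left@0.7"`).
#' @return Named numeric vector `pct_gm`, `pct_wm`, `pct_csf` in \[0, 100\].
#' @export
tissuePercentages <- function(map, seg, label = "object map") {
  stopifnot(is(map, "BrainMask"), is(seg, "TissueLabels"))
  .stopIfGridMismatch(map, seg, "map and segmentation")
  n <- sum(map@voxels)
  if (n == 0L)
    stop("empty object map: ", label, call. = FALSE)
  codes <- tissueCodes()
  labs <- seg@voxels[map@voxels]
  c(pct_gm = 100 * sum(labs == codes[["gm"]]) / n,
    pct_wm = 100 * sum(labs == codes[["wm"]]) / n,
    pct_csf = 100 * sum(labs == codes[["csf"]]) / n)
}

#' Asymmetry quotient
#'
#' The laterality quotient `AQ = (R - L) / (0.5 * (R + L))`, bounded in
#' \[-2, 2\]; positive values indicate a rightward bias and the bounds are
#' attained only when one side is zero.
#'
#' @param right,left nonnegative measurements (e.g. percent WM) for the
#'   right and left hemisphere; vectorized.
#' @return The asymmetry quotient(s).
#' @examples
#' asymmetryQuotient(75, 25)  #  1
#' asymmetryQuotient(0, 100)  # -2
#' @export
asymmetryQuotient <- function(right, left) {
  if (any(right < 0 | left < 0))
    stop("measurements must be nonnegative", call. = FALSE)
  if (any(right + left == 0))
    stop("asymmetry quotient undefined when R + L = 0", call. = FALSE)
  (right - left) / (0.5 * (right + left))
}

#' Bilateral volume of interest from a cluster
#'
#' Fuses a cluster's voxel set with its left-right mirror image, yielding
#' an exactly mirror-symmetric bilateral VOI suitable for per-hemisphere
#' tissue quantification.
#'
#' @param clusters a [ClusterSet].
#' @param id cluster id (row of [clusterTable()]), default the top
#'   cluster.
#' @param dims,voxelSizeMM grid geometry for the output mask; defaults are
#'   taken from a reference volume if supplied via `reference`.
#' @param reference optional volume object supplying the grid.
#' @return A symmetric [BrainMask].
#' @export
bilateralVOI <- function(clusters, id = 1L, reference = NULL,
                         dims = gridDim(reference),
                         voxelSizeMM = voxelSize(reference)) {
  stopifnot(is(clusters, "ClusterSet"))
  if (length(clusters) < id || id < 1L)
    stop("no cluster with id ", id, call. = FALSE)
  vox <- clusterVoxels(clusters)[[id]]
  if (nrow(vox) == 0L)
    stop("cluster voxel list is empty", call. = FALSE)
  m <- array(FALSE, dim = dims)
  m[vox] <- TRUE
  mask <- BrainMask(m, voxelSizeMM)
  fused <- mask@voxels | .flipArray(mask@voxels)
  initialize(mask, voxels = fused)
}

#' Correlate VOI tissue composition with atlas-map composition
#'
#' For every subject, computes the percentage of a tissue inside the
#' bilateral VOI and inside each thresholded atlas object map (left and
#' right maps pooled), then reports the Pearson correlation across
#' subjects for each threshold. Pairs with zero variance are flagged with
#' `NA` and a warning.
#'
#' @param segs list of per-subject [TissueLabels].
#' @param voi bilateral [BrainMask] from [bilateralVOI()].
#' @param atlasMaps named list (by threshold fraction) of
#'   `list(left=, right=)` map pairs from [thresholdAtlas()].
#' @param tissue `"gm"`, `"wm"` or `"csf"` (default `"gm"`).
#' @return data.frame with columns `fraction`, `r`, `p`, `n`.
#' @export
voiStructureCorrelation <- function(segs, voi, atlasMaps, tissue = "gm") {
  stopifnot(is.list(segs), length(segs) >= 4L, is(voi, "BrainMask"))
  col <- paste0("pct_", match.arg(tissue, c("gm", "wm", "csf")))
  pctVOI <- vapply(segs, function(s)
    tissuePercentages(voi, s, "bilateral VOI")[[col]], numeric(1))
  out <- lapply(names(atlasMaps), function(fr) {
    pair <- atlasMaps[[fr]]
    merged <- BrainMask(pair$left@voxels | pair$right@voxels,
                        pair$left@voxelSize)
    pctMap <- vapply(segs, function(s)
      tissuePercentages(merged, s, paste0("atlas@", fr))[[col]], numeric(1))
    if (stats::sd(pctVOI) == 0 || stats::sd(pctMap) == 0) {
      warning("zero variance at fraction ", fr,
              ": correlation undefined", call. = FALSE)
      return(data.frame(fraction = as.numeric(fr), r = NA_real_,
                        p = NA_real_, n = length(segs)))
    }
    ct <- stats::cor.test(pctVOI, pctMap)
    data.frame(fraction = as.numeric(fr), r = unname(ct$estimate),
               p = ct$p.value, n = length(segs))
  })
  do.call(rbind, out)
}

#' Per-subject tissue quantification across atlas thresholds
#'
#' Tidy table of tissue percentages per subject, threshold fraction and
#' hemisphere, plus white- and grey-matter asymmetry quotients.
#'
#' @param segs list of per-subject [TissueLabels].
#' @param atlasMaps named list (by fraction) of `list(left=, right=)`
#'   object-map pairs.
#' @param subjects optional subject ids.
#' @return data.frame with columns `subject`, `fraction`, `hemisphere`,
#'   `pct_gm`, `pct_wm`, `pct_csf`, and per subject/fraction `aq_wm`,
#'   `aq_gm` repeated on both hemisphere rows.
#' @export
quantifyCohort <- function(segs, atlasMaps,
                           subjects = sprintf("S%03d", seq_along(segs))) {
  rows <- list()
  for (fr in names(atlasMaps)) {
    pair <- atlasMaps[[fr]]
    for (si in seq_along(segs)) {
      pctL <- tissuePercentages(pair$left, segs[[si]], paste0("left@", fr))
      pctR <- tissuePercentages(pair$right, segs[[si]], paste0("right@", fr))
      aqWM <- asymmetryQuotient(pctR[["pct_wm"]], pctL[["pct_wm"]])
      aqGM <- asymmetryQuotient(pctR[["pct_gm"]], pctL[["pct_gm"]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[si], fraction = as.numeric(fr),
        hemisphere = c("left", "right"),
        pct_gm = c(pctL[["pct_gm"]], pctR[["pct_gm"]]),
        pct_wm = c(pctL[["pct_wm"]], pctR[["pct_wm"]]),
        pct_csf = c(pctL[["pct_csf"]], pctR[["pct_csf"]]),
        aq_wm = aqWM, aq_gm = aqGM, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
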