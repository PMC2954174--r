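#' @include AllClasses.R volume-ops.R
#' @useDynLib latermap, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Standardize an activation volume to its whole-brain mean
#'
#' Divides every voxel by the mean activation over the brain mask, so the
#' in-mask mean of the output is exactly 1 and global uptake or dose
#' differences between subjects cancel. Out-of-mask voxels are set to 0.
#'
#' @param v a [ScalarVolume].
#' @param brain a [BrainMask] on the same grid.
#' @return A standardized [ScalarVolume].
#' @export
standardize <- function(v, brain) {
  stopifnot(is(v, "ScalarVolume"), is(brain, "BrainMask"))
  .stopIfGridMismatch(v, brain, "volume and brain mask")
  m <- mean(v@voxels[brain@voxels])
  if (!is.finite(m) || m <= 0)
    stop("in-mask mean activation must be positive (got ", signif(m, 4), ")",
         call. = FALSE)
  vals <- array(0, dim = dim(v@voxels))
  vals[brain@voxels] <- v@voxels[brain@voxels] / m
  initialize(v, voxels = vals)
}

#' Flip-subtract difference volume
#'
#' Subtracts the left-right flipped image from the volume itself:
#' `D = v - flipLR(v)`. The result is exactly antisymmetric across the
#' mid-sagittal plane; positive values mark voxels more active than their
#' mirror twin.
#'
#' @param std a standardized [ScalarVolume].
#' @return An antisymmetric [ScalarVolume].
#' @export
differenceVolume <- function(std) {
  stopifnot(is(std, "ScalarVolume"))
  initialize(std, voxels = std@voxels - .flipArray(std@voxels))
}

#' Align a difference volume to the canonical hand orientation
#'
#' Puts every subject's contralateral hemisphere on the same side of the
#' grid so subjects can be pooled: difference volumes of left-hand
#' subjects are returned unchanged, those of right-hand subjects are
#' left-right flipped.
#'
#' @param D a difference [ScalarVolume].
#' @param hand `"left"` or `"right"` grasping hand.
#' @return A [ScalarVolume] in canonical orientation.
#' @export
alignHand <- function(D, hand) {
  if (!is.character(hand) || length(hand) != 1L ||
      !hand %in% c("left", "right"))
    stop("unknown hand label: ", paste(hand, collapse = ", "), call. = FALSE)
  if (hand == "left") D else flipLR(D)
}

#' Group one-sample t-map
#'
#' Voxelwise one-sample t statistic of the aligned per-subject difference
#' volumes against zero: `t = mean / (sd / sqrt(n))`, with the sample
#' standard deviation on `n - 1` degrees of freedom. Voxels whose
#' between-subject sd is zero are assigned t = 0 and flagged.
#'
#' @param diffs list of at least two aligned difference [ScalarVolume]s on
#'   one grid.
#' @return A [TMap].
#' @export
groupTMap <- function(diffs) {
  if (!is.list(diffs) || length(diffs) < 2L)
    stop("need at least 2 aligned difference volumes", call. = FALSE)
  stopifnot(all(vapply(diffs, is, logical(1), "ScalarVolume")))
  for (i in seq_along(diffs)[-1L])
    .stopIfGridMismatch(diffs[[1L]], diffs[[i]], "difference volumes")
  n <- length(diffs)
  d <- dim(diffs[[1L]]@voxels)
  mat <- vapply(diffs, function(v) as.vector(v@voxels), numeric(prod(d)))
  mu <- rowMeans(mat)
  ss <- rowSums((mat - mu)^2)
  sdv <- sqrt(ss / (n - 1L))
  zero <- sdv == 0
  tv <- numeric(length(mu))
  tv[!zero] <- mu[!zero] / (sdv[!zero] / sqrt(n))
  new("TMap",
      tvals = array(tv, dim = d),
      voxelSize = diffs[[1L]]@voxelSize,
      df = n - 1L, nSubjects = as.integer(n),
      zeroSD = array(zero, dim = d))
}

#' Critical t value
#'
#' Upper-tail quantile of Student's t distribution: the value a voxel's t
#' statistic must reach for one-tailed significance at level `alpha` with
#' `df` degrees of freedom.
#'
#' @param df degrees of freedom, >= 1.
#' @param alpha one-tailed significance level in (0, 1).
#' @return The critical t value.
#' @examples
#' criticalT(3, 0.01)  # 4.54 to two decimals
#' @export
criticalT <- function(df, alpha) {
  if (!is.numeric(df) || length(df) != 1L || df < 1)
    stop("'df' must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  stats::qt(1 - alpha, df)
}

#' Report cluster coordinates in table convention
#'
#' Converts a voxel index to reported millimetre coordinates: `x` is the
#' signed distance from the mid-sagittal plane, negative on the canonical
#' (contralateral) side of the aligned grid; `y` is the distance from the
#' most anterior in-mask voxel; `z` the distance from the most superior
#' in-mask voxel. `y` and `z` are therefore nonnegative inside the brain.
#'
#' @param voxel integer(3) voxel index (i, j, k), 1-based.
#' @param brain the [BrainMask] defining the anterior/superior origins.
#' @return Named numeric vector with elements `x`, `y`, `z` (mm).
#' @export
reportCoordinates <- function(voxel, brain) {
  stopifnot(is(brain, "BrainMask"))
  d <- gridDim(brain)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d))
    stop("voxel index outside the grid", call. = FALSE)
  vs <- brain@voxelSize
  # distance from the mid-sagittal plane, negated so the canonical
  # contralateral side (high-i columns after hand alignment) reports x < 0
  x <- -((voxel[1L] - 0.5) - d[1L] / 2) * vs[1L]
  occ <- which(brain@voxels, arr.ind = TRUE)
  if (nrow(occ) == 0L)
    stop("brain mask is empty", call. = FALSE)
  y <- (max(occ[, 2L]) - voxel[2L]) * vs[2L]
  z <- (max(occ[, 3L]) - voxel[3L]) * vs[3L]
  c(x = x, y = y, z = z)
}

#' Extract supra-threshold clusters from a t-map
#'
#' Thresholds the t-map at `tThreshold`, labels connected components of
#' the supra-threshold set, discards components smaller than
#' `minExtentMM3` (converted to a voxel count by the voxel volume, rounded
#' up), and reports each surviving cluster's peak t, reported coordinates,
#' and extent, sorted by peak t descending. A cluster is attributed to the
#' contralateral hemisphere when the reported x of its peak is negative.
#' Only positive (supra-threshold) clusters are extracted: the t-map is
#' antisymmetric, so every cluster has a redundant mirrored negative twin.
#'
#' When an `effect` volume (typically the subject-average difference
#' volume) is supplied, each record also carries the within-cluster peak
#' of that effect map (`effect_i/j/k` and reported `effect_x/y/z`): with
#' few subjects the location of the maximum t is unstable because the
#' voxelwise standard-deviation estimate has very few degrees of freedom,
#' whereas the effect peak localizes the activation reliably.
#'
#' @param tmap a [TMap].
#' @param brain the [BrainMask] used for coordinate reporting.
#' @param tThreshold positive t threshold.
#' @param minExtentMM3 minimum cluster extent in mm^3.
#' @param connectivity neighborhood definition: 6, 18 or 26 (default).
#' @param effect optional [ScalarVolume] effect map on the same grid used
#'   to localize each cluster's effect peak.
#' @return A [ClusterSet]; empty if nothing survives.
#' @export
extractClusters <- function(tmap, brain, tThreshold = 4.54,
                            minExtentMM3 = 72, connectivity = 26L,
                            effect = NULL) {
  stopifnot(is(tmap, "TMap"), is(brain, "BrainMask"))
  if (tThreshold <= 0 || minExtentMM3 <= 0)
    stop("thresholds must be positive", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  d <- dim(tmap@tvals)
  supra <- tmap@tvals >= tThreshold
  vv <- voxelVolume(tmap)
  minVox <- ceiling(minExtentMM3 / vv)
  emptySet <- function() new("ClusterSet",
    table = data.frame(cluster = integer(0), peak_t = numeric(0),
                       x = numeric(0), y = numeric(0), z = numeric(0),
                       volume_mm3 = numeric(0), n_voxels = integer(0),
                       hemisphere = character(0), stringsAsFactors = FALSE),
    voxels = list(), tThreshold = tThreshold, minExtentMM3 = minExtentMM3,
    connectivity = connectivity)
  if (!any(supra)) return(emptySet())
  labels <- .labelComponents(as.vector(supra), as.integer(d), connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= minVox)
  if (!length(keep)) return(emptySet())
  rows <- vector("list", length(keep))
  voxl <- vector("list", length(keep))
  for (ci in seq_along(keep)) {
    idx <- which(labels == keep[ci])
    vox <- arrayInd(idx, d)
    peak <- idx[which.max(tmap@tvals[idx])]
    pk <- arrayInd(peak, d)[1L, ]
    co <- reportCoordinates(pk, brain)
    row <- data.frame(
      cluster = ci, peak_t = tmap@tvals[peak],
      x = co[["x"]], y = co[["y"]], z = co[["z"]],
      volume_mm3 = length(idx) * vv, n_voxels = length(idx),
      hemisphere = if (co[["x"]] < 0) "contralateral" else "ipsilateral",
      peak_i = pk[1L], peak_j = pk[2L], peak_k = pk[3L],
      stringsAsFactors = FALSE)
    if (!is.null(effect)) {
      ep <- idx[which.max(effect@voxels[idx])]
      epk <- arrayInd(ep, d)[1L, ]
      eco <- reportCoordinates(epk, brain)
      row$effect_i <- epk[1L]; row$effect_j <- epk[2L]
      row$effect_k <- epk[3L]
      row$effect_x <- eco[["x"]]; row$effect_y <- eco[["y"]]
      row$effect_z <- eco[["z"]]
    }
    rows[[ci]] <- row
    voxl[[ci]] <- vox
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$peak_t, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$cluster <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("ClusterSet", table = tab, voxels = voxl[ord],
      tThreshold = tThreshold, minExtentMM3 = minExtentMM3,
      connectivity = connectivity)
}

#' Run the full activation-asymmetry stage for a cohort
#'
#' Convenience wrapper chaining [standardize()], [smoothIsotropic()],
#' [differenceVolume()], [alignHand()], [groupTMap()] and
#' [extractClusters()] over a list of subject volumes.
#'
#' @param volumes list of raw activation [ScalarVolume]s.
#' @param hands character vector of grasping hands, one per subject.
#' @param brain shared [BrainMask].
#' @param fwhmMM smoothing kernel FWHM in mm (default 6).
#' @param tThreshold,minExtentMM3,connectivity passed to
#'   [extractClusters()].
#' @return List with elements `tmap` ([TMap]), `meanDiff` (the
#'   subject-average difference [ScalarVolume]) and `clusters`
#'   ([ClusterSet], annotated with effect peaks).
#' @export
petAsymmetry <- function(volumes, hands, brain, fwhmMM = 6,
                         tThreshold = 4.54, minExtentMM3 = 72,
                         connectivity = 26L) {
  stopifnot(length(volumes) == length(hands))
  diffs <- mapply(function(v, h) {
    alignHand(differenceVolume(smoothIsotropic(standardize(v, brain),
                                               fwhmMM)), h)
  }, volumes, hands, SIMPLIFY = FALSE)
  tmap <- groupTMap(diffs)
  avg <- ScalarVolume(Reduce(`+`, lapply(diffs, voxels)) / length(diffs),
                      diffs[[1L]]@voxelSize)
  list(tmap = tmap, meanDiff = avg,
       clusters = extractClusters(tmap, brain, tThreshold, minExtentMM3,
                                  connectivity, effect = avg))
}
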