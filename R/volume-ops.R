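#' @include AllClasses.R AllGenerics.R
NULL

.flipArray <- function(a) {
  a[rev(seq_len(dim(a)[1L])), , , drop = FALSE]
}

#' @rdname flipLR
#' @export
setMethod("flipLR", "ScalarVolume", function(x) {
  initialize(x, voxels = .flipArray(x@voxels))
})

#' @rdname flipLR
#' @export
setMethod("flipLR", "BrainMask", function(x) {
  initialize(x, voxels = .flipArray(x@voxels))
})

#' @rdname flipLR
#' @export
setMethod("flipLR", "TissueLabels", function(x) {
  initialize(x, voxels = .flipArray(x@voxels))
})

# Discrete Gaussian kernel for one axis, truncated at 4 sigma and
# renormalized so that convolution preserves the total sum of a compactly
# supported volume.
.gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

# Convolve along one axis. The volume is permuted so the target axis is
# first, collapsed to a matrix, and the kernel applied as a sum of
# row-shifted copies. At the faces the truncated kernel is renormalized by
# the in-bounds weight, so constants are exact fixed points everywhere;
# the renormalization is mirror-symmetric, so left-right antisymmetry is
# preserved, and it only acts within a kernel radius of the faces, so the
# total sum of a compactly supported volume is conserved.
.convolveAxis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (t in seq.int(-r, r)) {
    w <- k[t + r + 1L]
    src <- seq_len(n) - t
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  out <- out / wsum
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Isotropic Gaussian smoothing
#'
#' Low-pass filters a volume with a separable Gaussian kernel whose
#' full-width-at-half-maximum is `fwhmMM` millimetres on every axis. The
#' per-axis standard deviation in voxels is `fwhmMM / (2 sqrt(2 log 2)) /
#' voxelSize`. The kernel is truncated at four standard deviations and
#' renormalized at the grid faces, so constant volumes are exact fixed
#' points, left-right antisymmetry is preserved, and the total sum of a
#' compactly supported volume is conserved.
#'
#' @param v a [ScalarVolume].
#' @param fwhmMM kernel full width at half maximum in mm; 0 returns the
#'   input unchanged.
#' @return A smoothed [ScalarVolume] on the same grid.
#' @examples
#' v <- ScalarVolume(array(rnorm(4096), dim = c(16, 16, 16)), c(2, 2, 2))
#' s <- smoothIsotropic(v, 6)
#' @export
smoothIsotropic <- function(v, fwhmMM) {
  stopifnot(is(v, "ScalarVolume"))
  if (!is.numeric(fwhmMM) || length(fwhmMM) != 1L || !is.finite(fwhmMM) ||
      fwhmMM < 0)
    stop("'fwhmMM' must be a single finite value >= 0", call. = FALSE)
  if (fwhmMM == 0) return(v)
  sigmaMM <- fwhmMM / (2 * sqrt(2 * log(2)))
  a <- v@voxels
  for (axis in 1:3) {
    k <- .gaussKernel1d(sigmaMM / v@voxelSize[axis])
    a <- .convolveAxis(a, k, axis)
  }
  initialize(v, voxels = a)
}

#' Hemisphere masks
#'
#' Splits the grid of a volume at the mid-sagittal plane into left and
#' right hemisphere masks. With the left-to-right axis convention, the
#' left hemisphere occupies columns `1..nx/2` and the right hemisphere
#' columns `nx/2+1..nx`; the two masks partition the grid and are mapped
#' onto each other by [flipLR()].
#'
#' @param x any volume object carrying a grid ([BrainVolume], [TMap] or
#'   [OverlapAtlas]).
#' @return A list with [BrainMask] elements `left` and `right`.
#' @examples
#' v <- ScalarVolume(array(0, dim = c(4, 2, 2)), c(1, 1, 1))
#' h <- hemisphereMasks(v)
#' sum(voxels(h$left) & voxels(h$right))  # disjoint
#' @export
hemisphereMasks <- function(x) {
  d <- gridDim(x)
  half <- d[1L] %/% 2L
  left <- array(FALSE, dim = d)
  left[seq_len(half), , ] <- TRUE
  list(
    left = BrainMask(left, voxelSize(x)),
    right = BrainMask(!left, voxelSize(x))
  )
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject substream seed derived from a master seed, so
# adding a subject never perturbs the streams of earlier subjects. Kept
# within the 32-bit integer range.
spawnSeed <- function(master, index, stream = 0L) {
  as.integer((as.numeric(master) %% 65011 * 31627 +
                as.numeric(stream) * 7907 +
                as.numeric(index) * 104729 + 13) %% 2147483647)
}

# Millimetre voxel-center coordinates relative to the grid center. The x
# coordinate is measured from the mid-sagittal plane (negative = left
# hemisphere) and is exactly negated by flipLR.
gridCoordsMM <- function(dims, voxelSize) {
  ax <- function(n, s) (seq_len(n) - (n + 1) / 2) * s
  list(
    x = ax(dims[1L], voxelSize[1L]),
    y = ax(dims[2L], voxelSize[2L]),
    z = ax(dims[3L], voxelSize[3L])
  )
}

# Full coordinate arrays (each dims-shaped) for vectorized geometry.
gridCoordArrays <- function(dims, voxelSize) {
  cc <- gridCoordsMM(dims, voxelSize)
  list(
    x = array(cc$x, dim = dims),
    y = array(rep(cc$y, each = dims[1L]), dim = dims),
    z = array(rep(cc$z, each = dims[1L] * dims[2L]), dim = dims)
  )
}
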