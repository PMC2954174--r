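test_that("standardization normalizes the in-mask mean to one and is scale invariant", {
  m <- BrainMask(array(TRUE, dim = c(2, 1, 1)), c(1, 1, 1))
  v <- ScalarVolume(array(c(2, 4), dim = c(2, 1, 1)), c(1, 1, 1))
  s <- standardize(v, m)
  expect_equal(as.vector(voxels(s)), c(2 / 3, 4 / 3))
  expect_equal(mean(voxels(s)[voxels(m)]), 1)

  set.seed(3)
  vol <- randomScalarVolume(c(8L, 8L, 8L))
  vol@voxels <- abs(vol@voxels) + 1
  mask <- BrainMask(array(runif(512) < 0.6, dim = c(8, 8, 8)), c(1, 1, 1))
  s1 <- standardize(vol, mask)
  s2 <- standardize(ScalarVolume(7.3 * voxels(vol), c(1, 1, 1)), mask)
  expect_equal(voxels(s1), voxels(s2), tolerance = 1e-12)

  cv <- ScalarVolume(array(4.2, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_true(all(voxels(standardize(cv, mask))[voxels(mask)] == 1))
  neg <- ScalarVolume(array(-1, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_error(standardize(neg, mask), "positive")
})

test_that("difference volumes are exactly antisymmetric with zero total", {
  line <- ScalarVolume(array(c(1, 2, 3, 4), dim = c(4, 1, 1)), c(1, 1, 1))
  D <- differenceVolume(line)
  expect_equal(as.vector(voxels(D)), c(-3, -1, 1, 3))
  expect_equal(sum(voxels(D)), 0)

  set.seed(9)
  v <- randomScalarVolume(c(10L, 8L, 6L))
  D2 <- differenceVolume(v)
  expect_equal(voxels(flipLR(D2)), -voxels(D2))
  sym <- ScalarVolume(voxels(v) + voxels(flipLR(v)), voxelSize(v))
  expect_true(all(voxels(differenceVolume(sym)) == 0))
})

test_that("hand alignment flips right-hand subjects only and is involutive", {
  set.seed(2)
  D <- differenceVolume(randomScalarVolume(c(8L, 6L, 4L)))
  expect_identical(voxels(alignHand(D, "left")), voxels(D))
  expect_identical(voxels(alignHand(alignHand(D, "right"), "right")),
                   voxels(D))
  expect_identical(voxels(alignHand(D, "right")), voxels(flipLR(D)))
  expect_error(alignHand(D, "ambidextrous"), "hand")
})

test_that("group t-map matches the hand-computed one-sample t", {
  base <- array(0, dim = c(4, 2, 2))
  vals <- c(1, 1, 1, 3)
  diffs <- lapply(vals, function(x) {
    a <- base; a[2, 1, 1] <- x
    ScalarVolume(a, c(1, 1, 1))
  })
  tm <- groupTMap(diffs)
  expect_equal(tm@tvals[2, 1, 1], 3.0)
  expect_equal(tm@df, 3L)
  # sd = 0 voxels are flagged and set to zero
  expect_true(tm@zeroSD[1, 1, 1])
  expect_equal(tm@tvals[1, 1, 1], 0)

  zeros <- lapply(1:3, function(i) ScalarVolume(base, c(1, 1, 1)))
  expect_true(all(groupTMap(zeros)@tvals == 0))
  expect_error(groupTMap(diffs[1]), "at least 2")
})

test_that("t-maps of antisymmetric inputs are antisymmetric", {
  set.seed(13)
  diffs <- lapply(1:4, function(i)
    smoothIsotropic(differenceVolume(randomScalarVolume(c(12L, 10L, 8L),
                                                        c(2, 2, 2))), 6))
  tm <- groupTMap(diffs)
  flipped <- tm@tvals[rev(seq_len(12)), , ]
  expect_lt(max(abs(tm@tvals + flipped)), 1e-6)
})

test_that("critical t reproduces tabulated quantiles", {
  expect_equal(round(criticalT(3, 0.01), 2), 4.54)
  expect_equal(criticalT(1, 0.25), 1.0, tolerance = 1e-12)  # tan(pi/4)
  expect_equal(criticalT(1e9, 0.5), 0, tolerance = 1e-6)
  expect_error(criticalT(0, 0.05), "df")
  expect_error(criticalT(3, 1.5), "alpha")
})

test_that("cluster extraction applies the extent rule", {
  tv <- array(0, dim = c(20, 10, 10))
  tv[3:7, 3:6, 3:7] <- 5      # 100 voxels = 100 mm^3 at 1 mm voxels
  tv[12:16, 8:9, 3:7] <- 6    # 50 voxels
  tm <- new("TMap", tvals = tv, voxelSize = c(1, 1, 1), df = 3L,
            nSubjects = 4L, zeroSD = array(FALSE, dim = dim(tv)))
  brain <- BrainMask(array(TRUE, dim = dim(tv)), c(1, 1, 1))
  cs <- extractClusters(tm, brain, tThreshold = 4.54, minExtentMM3 = 72)
  expect_equal(length(cs), 1L)
  expect_equal(clusterTable(cs)$n_voxels, 100L)

  none <- extractClusters(new("TMap", tvals = array(0, dim = dim(tv)),
                              voxelSize = c(1, 1, 1), df = 3L,
                              nSubjects = 4L,
                              zeroSD = array(FALSE, dim = dim(tv))),
                          brain)
  expect_equal(length(none), 0L)
})

test_that("cluster voxel sets match a brute-force flood-fill oracle", {
  set.seed(31)
  brain <- BrainMask(array(TRUE, dim = c(16, 16, 16)), c(1, 1, 1))
  for (rep in 1:8) {
    for (conn in c(6L, 18L, 26L)) {
      tv <- array(rnorm(16^3), dim = c(16, 16, 16)) * 10
      tm <- new("TMap", tvals = tv, voxelSize = c(1, 1, 1), df = 3L,
                nSubjects = 4L, zeroSD = array(FALSE, dim = dim(tv)))
      cs <- extractClusters(tm, brain, tThreshold = 8, minExtentMM3 = 1,
                            connectivity = conn)
      oracle <- componentSets(oracleLabelComponents(tv >= 8, conn))
      got <- lapply(clusterVoxels(cs), function(v)
        sort((v[, 3] - 1) * 256 + (v[, 2] - 1) * 16 + v[, 1]))
      got <- got[order(vapply(got, min, numeric(1)))]
      expect_equal(got, oracle)
    }
  }
})

test_that("reported coordinates follow the table convention", {
  m <- array(FALSE, dim = c(8, 8, 8))
  m[3:6, 2:7, 2:6] <- TRUE
  brain <- BrainMask(m, c(2, 2, 2))
  # first column on the canonical (high-i) side of the midline: x = -1
  expect_equal(reportCoordinates(c(5, 4, 4), brain)[["x"]], -1)
  expect_equal(reportCoordinates(c(4, 4, 4), brain)[["x"]], 1)
  # most anterior / most superior in-mask voxel maps to 0
  expect_equal(reportCoordinates(c(5, 7, 4), brain)[["y"]], 0)
  expect_equal(reportCoordinates(c(5, 4, 6), brain)[["z"]], 0)
  # mirrored voxels: equal magnitude, opposite sign
  a <- reportCoordinates(c(2, 4, 4), brain)[["x"]]
  b <- reportCoordinates(c(7, 4, 4), brain)[["x"]]
  expect_equal(a, -b)
  expect_error(reportCoordinates(c(9, 1, 1), brain), "outside")
})
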