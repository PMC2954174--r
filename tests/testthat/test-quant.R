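segFromCounts <- function(dims, wmIdx, gmIdx, csfIdx = integer(0),
                          voxelSize = c(1, 1, 1)) {
  codes <- tissueCodes()
  a <- array(codes[["background"]], dim = dims)
  a[wmIdx] <- codes[["wm"]]; a[gmIdx] <- codes[["gm"]]
  a[csfIdx] <- codes[["csf"]]
  TissueLabels(a, voxelSize)
}

test_that("tissue percentages divide by the full map volume", {
  dims <- c(10, 10, 1)
  map <- BrainMask(array(TRUE, dim = dims), c(1, 1, 1))
  seg <- segFromCounts(dims, wmIdx = 1:60, gmIdx = 61:100)
  pct <- tissuePercentages(map, seg)
  expect_equal(unname(pct), c(40, 60, 0))

  allWM <- segFromCounts(dims, wmIdx = 1:100, gmIdx = integer(0))
  expect_equal(unname(tissuePercentages(map, allWM)), c(0, 100, 0))

  empty <- BrainMask(array(FALSE, dim = dims), c(1, 1, 1))
  expect_error(tissuePercentages(empty, seg, label = "left@0.7"), "left@0.7")
})

test_that("two-compartment closure: zero CSF forces GM + WM = 100 and r = -1", {
  set.seed(41)
  dims <- c(8, 8, 8)
  map <- BrainMask(array(c(TRUE, FALSE), dim = dims), c(1, 1, 1))
  gm <- numeric(12); wm <- numeric(12)
  for (i in 1:12) {
    lab <- array(sample(c(1L, 2L), prod(dims), TRUE,
                        prob = c(i / 13, 1 - i / 13)), dim = dims)
    seg <- TissueLabels(lab, c(1, 1, 1))
    pct <- tissuePercentages(map, seg)
    expect_equal(pct[["pct_gm"]] + pct[["pct_wm"]], 100, tolerance = 1e-12)
    gm[i] <- pct[["pct_gm"]]; wm[i] <- pct[["pct_wm"]]
  }
  expect_equal(pearsonCorrelation(gm, wm)$r, -1)
})

test_that("asymmetry quotient matches the laterality-quotient convention", {
  expect_equal(asymmetryQuotient(50, 50), 0)
  expect_equal(asymmetryQuotient(75, 25), 1.0)
  expect_equal(asymmetryQuotient(0, 100), -2.0)
  expect_equal(asymmetryQuotient(100, 0), 2.0)
  # antisymmetry and bounds on random pairs
  set.seed(43)
  r <- runif(50, 0, 100); l <- runif(50, 0, 100)
  expect_equal(asymmetryQuotient(r, l), -asymmetryQuotient(l, r))
  expect_true(all(abs(asymmetryQuotient(r, l)) <= 2))
  expect_error(asymmetryQuotient(0, 0), "undefined")
  expect_error(asymmetryQuotient(-1, 2), "nonnegative")
})

test_that("percentages are invariant under uniform grid refinement", {
  set.seed(47)
  dims <- c(6, 6, 6)
  m <- array(runif(prod(dims)) < 0.5, dim = dims)
  lab <- array(sample(0:3, prod(dims), TRUE), dim = dims)
  refine <- function(a) a[rep(1:6, each = 2), rep(1:6, each = 2),
                          rep(1:6, each = 2)]
  coarse <- tissuePercentages(BrainMask(m, c(2, 2, 2)),
                              TissueLabels(lab, c(2, 2, 2)))
  fine <- tissuePercentages(BrainMask(refine(m), c(1, 1, 1)),
                            TissueLabels(refine(lab), c(1, 1, 1)))
  expect_equal(coarse, fine)
})

test_that("bilateral VOIs are exactly mirror-symmetric", {
  tv <- array(0, dim = c(12, 8, 8))
  tv[9:11, 3:5, 3:5] <- 6   # one-sided cluster, 27 voxels
  tm <- new("TMap", tvals = tv, voxelSize = c(2, 2, 2), df = 3L,
            nSubjects = 4L, zeroSD = array(FALSE, dim = dim(tv)))
  brain <- BrainMask(array(TRUE, dim = dim(tv)), c(2, 2, 2))
  cs <- extractClusters(tm, brain, tThreshold = 4.54, minExtentMM3 = 72)
  voi <- bilateralVOI(cs, 1L, reference = brain)
  expect_identical(voxels(flipLR(voi)), voxels(voi))
  hemi <- hemisphereMasks(voi)
  expect_equal(sum(voxels(voi) & voxels(hemi$left)),
               sum(voxels(voi) & voxels(hemi$right)))
  # cluster and mirror disjoint -> double the voxel count
  expect_equal(sum(voxels(voi)), 2L * clusterTable(cs)$n_voxels[1])

  # an already-symmetric cluster is idempotent under fusion
  tv2 <- tv; tv2[rev(seq_len(12)), , ] <- pmax(tv[rev(seq_len(12)), , ], tv)
  tm2 <- new("TMap", tvals = tv2, voxelSize = c(2, 2, 2), df = 3L,
             nSubjects = 4L, zeroSD = array(FALSE, dim = dim(tv)))
  cs2 <- extractClusters(tm2, brain, tThreshold = 4.54, minExtentMM3 = 72)
  voi2 <- bilateralVOI(cs2, 1L, reference = brain)
  expect_lte(sum(voxels(voi2)), 2L * clusterTable(cs2)$n_voxels[1])
})

test_that("VOI-atlas correlation is one for identical maps and recovers implanted structure", {
  cfg <- smallConfig(nAtlas = 12L)
  cohort <- simulateCohort(cfg, seed = 11)
  atlas <- sumTracings(cohort@tracings)
  maps <- list("0.5" = thresholdAtlas(atlas, 0.5))
  merged <- BrainMask(voxels(maps[["0.5"]]$left) | voxels(maps[["0.5"]]$right),
                      voxelSize(atlas))
  self <- voiStructureCorrelation(cohort@segmentations, merged, maps)
  expect_equal(self$r, 1, tolerance = 1e-12)

  # knob-overlapping VOI correlates positively at every threshold
  maps3 <- lapply(c(0.3, 0.5, 0.7), function(f) thresholdAtlas(atlas, f))
  names(maps3) <- c("0.3", "0.5", "0.7")
  res <- petAsymmetry(cohort@pet, cohort@hands, cohort@brainMask)
  voi <- bilateralVOI(res$clusters, 1L, reference = cohort@brainMask)
  rec <- voiStructureCorrelation(cohort@segmentations, voi, maps3)
  expect_true(all(rec$r > 0))
})

test_that("a VOI away from the tracing shows no structural correlation", {
  cfg <- smallConfig(nAtlas = 20L)
  rs <- vapply(1:10, function(s) {
    cohort <- simulateCohort(cfg, seed = s)
    atlas <- sumTracings(cohort@tracings)
    maps <- list("0.3" = thresholdAtlas(atlas, 0.3))
    # symmetric control VOI near the midline, outside the knob region
    ctrl <- array(FALSE, dim = gridDim(cohort@brainMask))
    ctrl[11:14, 8:11, 8:11] <- TRUE
    voi <- BrainMask(ctrl, voxelSize(cohort@brainMask))
    out <- suppressWarnings(
      voiStructureCorrelation(cohort@segmentations, voi, maps))
    out$r
  }, numeric(1))
  expect_lt(mean(abs(rs), na.rm = TRUE), 0.2)
})
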