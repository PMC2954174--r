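test_that("brain mask is symmetric, nonempty and occupies 30-60% of the grid", {
  cfg <- phantomConfig()
  mask <- makeBrainMask(cfg)
  expect_identical(voxels(flipLR(mask)), voxels(mask))
  frac <- sum(voxels(mask)) / prod(gridDim(mask))
  expect_gt(frac, 0.30)
  expect_lt(frac, 0.60)
  expect_identical(voxels(makeBrainMask(cfg)), voxels(mask))
  expect_error(phantomConfig(maskSemiAxesMM = c(200, 10, 10)), "exceeds")
})

test_that("activation volumes place the blob contralaterally and are reproducible", {
  cfg <- smallConfig(noiseSD = 0)
  mask <- makeBrainMask(cfg)
  # amplitude 0, noise 0 -> constant 1 inside the mask, 0 outside
  flat <- makePETSubject(smallConfig(noiseSD = 0, activationAmplitude = 0),
                         "left", 1, mask)
  expect_true(all(voxels(flat)[voxels(mask)] == 1))
  expect_true(all(voxels(flat)[!voxels(mask)] == 0))

  # left hand -> peak in the right-hemisphere columns
  v <- makePETSubject(cfg, "left", 1, mask)
  pk <- arrayInd(which.max(voxels(v)), gridDim(v))
  expect_gt(pk[1], gridDim(v)[1] / 2)
  v2 <- makePETSubject(cfg, "right", 1, mask)
  pk2 <- arrayInd(which.max(voxels(v2)), gridDim(v2))
  expect_lte(pk2[1], gridDim(v2)[1] / 2)

  noisy <- smallConfig()
  expect_identical(voxels(makePETSubject(noisy, "left", 9, mask)),
                   voxels(makePETSubject(noisy, "left", 9, mask)))
  expect_error(makePETSubject(cfg, "both", 1, mask), "hand")
})

test_that("tracings are bilateral and identical cohorts arise at zero jitter", {
  cfg0 <- smallConfig(tracingJitterMM = 0)
  mask <- makeBrainMask(cfg0)
  # freeze the scale factor too: jitter 0 still draws scale, so compare
  # overlap structure instead at scale-variability only
  tr <- lapply(1:5, function(i) makeTracing(cfg0, i, mask))
  hemi <- hemisphereMasks(tr[[1]])
  for (t in tr) {
    expect_gt(sum(voxels(t) & voxels(hemi$left)), 0)
    expect_gt(sum(voxels(t) & voxels(hemi$right)), 0)
  }
  expect_identical(voxels(makeTracing(cfg0, 3, mask)),
                   voxels(makeTracing(cfg0, 3, mask)))
})

test_that("larger tracing jitter shrinks the high-threshold atlas in expectation", {
  volAt <- function(jitter, seeds) {
    cfg <- smallConfig(tracingJitterMM = jitter, nAtlas = 12L)
    mask <- makeBrainMask(cfg)
    mean(vapply(seeds, function(s) {
      tr <- lapply(1:12, function(i)
        suppressWarnings(makeTracing(cfg, s * 1000 + i, mask)))
      atlas <- sumTracings(tr)
      maps <- suppressWarnings(thresholdAtlas(atlas, 0.7))
      atlasVolume(maps$left) + atlasVolume(maps$right)
    }, numeric(1)))
  }
  expect_gt(volAt(0.5, 1:20), volAt(4, 1:20))
})

test_that("segmentation implants the requested white-matter asymmetry", {
  cfg <- smallConfig(csfFrac = 0)
  mask <- makeBrainMask(cfg)
  aqOf <- function(asym, seeds) {
    vapply(seeds, function(s) {
      tr <- makeTracing(cfg, s, mask)
      seg <- makeSegmentation(cfg, tr, s + 5000, asym = asym,
                              brainMask = mask)
      hemi <- hemisphereMasks(tr)
      pctL <- tissuePercentages(BrainMask(voxels(tr) & voxels(hemi$left),
                                          voxelSize(tr)), seg)
      pctR <- tissuePercentages(BrainMask(voxels(tr) & voxels(hemi$right),
                                          voxelSize(tr)), seg)
      asymmetryQuotient(pctR[["pct_wm"]], pctL[["pct_wm"]])
    }, numeric(1))
  }
  null <- aqOf(0, 1:30)
  expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(length(null)))
  expect_gt(mean(aqOf(0.5, 1:30)), 0.3)
  seg <- makeSegmentation(cfg, makeTracing(cfg, 1, mask), 2,
                          brainMask = mask)
  expect_true(all(voxels(seg) %in% 0:3))
  expect_error(makeSegmentation(cfg, makeTracing(cfg, 1, mask), 2,
                                asym = 3, brainMask = mask), "-2")
})

test_that("behavior links error counts to the implanted asymmetry", {
  cfg <- smallConfig()
  # no handedness effect: both hands share the same expected error count
  cfg0 <- smallConfig(handednessEffect = 0)
  errs <- t(vapply(1:200, function(s) makeBehavior(cfg0, -0.5, s),
                   numeric(2)))
  expect_lt(abs(mean(errs[, 1]) - mean(errs[, 2])),
            3 * sd(errs[, 1] - errs[, 2]) / sqrt(200))
  expect_true(all(errs >= 0 & errs <= cfg0@trialsPerHand))

  # leftward WM bias with a positive effect -> negative mean HI
  meanHI <- vapply(1:20, function(rep) {
    his <- vapply(1:60, function(i) {
      e <- makeBehavior(cfg, -0.4, rep * 100 + i)
      handednessIndex(e[["err_right"]], e[["err_left"]])
    }, numeric(1))
    mean(his, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(meanHI < 0))
})

test_that("cohorts are deterministic and extending one preserves early subjects", {
  cfg <- smallConfig(nAtlas = 6L)
  a <- simulateCohort(cfg, seed = 5)
  b <- simulateCohort(cfg, seed = 5)
  expect_identical(voxels(a@pet[[1]]), voxels(b@pet[[1]]))
  expect_identical(a@behavior, b@behavior)
  expect_identical(a@wmAsym, b@wmAsym)

  bigger <- simulateCohort(smallConfig(nAtlas = 9L), seed = 5)
  expect_identical(voxels(bigger@tracings[[4]]), voxels(a@tracings[[4]]))
  expect_identical(bigger@wmAsym[1:6], a@wmAsym)
  expect_identical(bigger@behavior$err_right[1:6], a@behavior$err_right)
})
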