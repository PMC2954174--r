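# latermap

Hemispheric laterality mapping of functional brain activation and
motor-hand anatomy in R.

## What it does, and for whom

`latermap` is for researchers who study handedness and brain asymmetry
with registered 3-D volumes. It implements the full analysis chain
connecting three kinds of laterality:

- **Functional**: voxelwise *flip-subtract* asymmetry mapping. Each
  subject's activation volume is standardized to its whole-brain mean,
  smoothed (6 mm FWHM Gaussian), and its left-right mirror image
  subtracted: `D = v − flipLR(v)`. Subjects are aligned so the
  hemisphere contralateral to the acting hand shares one grid side, and
  a voxelwise one-sample t-map `t = mean(D) / (sd(D)/√n)` with
  `df = n − 1` is thresholded at t ≥ 4.54 (the one-tailed p = .01
  critical value at df = 3) with a minimum cluster extent of 72 mm³.
- **Anatomical**: a probabilistic atlas of a traced region (e.g. the
  motor-hand "knob" of the precentral gyrus). Per-subject binary
  tracings are summed into a voxelwise overlap count and thresholded at
  fractional criteria (30/50/70%, i.e. at least
  `round(fraction · n)` subjects), then grey/white-matter composition is
  quantified per hemisphere and summarized as asymmetry quotients
  `AQ = (R − L)/(0.5(R + L))` (positive = rightward, bounded in
  [−2, 2]).
- **Behavioral**: handedness indices from per-hand grasping error
  counts, `HI = (errR − errL)/(errR + errL)` (negative = better right
  hand), with a population-level one-sample t test, Pearson
  structure-behavior correlations, and a two-way mixed-design ANOVA
  (handedness group × atlas threshold) on the WM asymmetry quotients.

Because raw scans of this kind are rarely shareable, the package ships a
synthetic brain-phantom generator (`simulateCohort()`) that produces
whole cohorts — activation volumes with a contralateral blob, jittered
bilateral tracings, tissue segmentations with an implanted WM asymmetry,
and error counts linked to that asymmetry — so the entire pipeline can
be exercised, validated and benchmarked without any data downloads.

Volumes are S4 objects (`ScalarVolume`, `BrainMask`, `TissueLabels`)
read and written as NIfTI-1 via RNifti, on a fixed left→right /
posterior→anterior / inferior→superior axis convention with an even
number of left-right columns (so the mid-sagittal plane lies exactly
between the two central voxel columns and flipping is an exact
involution).

## Worked example

```r
library(latermap)

cfg <- phantomConfig(nAtlas = 20L)   # 4 activation + 20 anatomy subjects
res <- runPipeline(cfg, seed = 42)

head(clusterTable(res$clusters)[, c("cluster","peak_t","x","y","z",
                                    "volume_mm3","hemisphere")], 3)
#>   cluster    peak_t   x  y  z volume_mm3    hemisphere
#> 1       1 135.38033 -17 48 26      10928 contralateral
#> 2       2  58.64809  49 60 26        272   ipsilateral
#> 3       3  50.85778 -61 76 30        432 contralateral

res$atlasVolumes
#>   fraction hemisphere  mm3
#> 1      0.3       left 2480
#> 2      0.3      right 2552
#> 3      0.5       left 1800
#> 4      0.5      right 1888
#> 5      0.7       left 1256
#> 6      0.7      right 1288

res$stats$gm_wm_correlation
#>   fraction          r            p  n
#> 1      0.3 -0.9939498 1.009234e-18 20
#> 2      0.5 -0.9925753 6.339438e-18 20
#> 3      0.7 -0.9829435 1.090907e-14 20

str(res$stats$handedness_threshold_interaction)
#> List of 4
#>  $ F  : num 7.01
#>  $ df1: num 2
#>  $ df2: num 32
#>  $ p  : num 0.00298
```

Reading the output: the top cluster sits on the contralateral side
(x = −17 mm from the midline, negative by the reporting convention) at
the implanted knob location and dwarfs the noise clusters in extent
(10 928 mm³). Atlas object-map volumes shrink monotonically as the
overlap criterion rises from 30% to 70% in both hemispheres. GM and WM
percentages are almost perfectly anticorrelated (the maps contain mostly
the two cortical compartments), and the handedness × threshold
interaction on the WM asymmetry quotient is recovered
(F(2, 32) = 7.01, p = .003): right-performing subjects carry more
leftward WM asymmetry, the implanted structure-behavior link.

`runPipeline(..., outDir = "out/")` additionally writes `clusters.csv`,
`atlas_volumes.csv`, `quant.csv`, `behavior.csv`, `stats.json` and a
reproducibility manifest; identical seed and configuration give
byte-identical outputs.

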