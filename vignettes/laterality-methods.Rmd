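---
title: "Methods: hemispheric laterality mapping with latermap"
author: "latermap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric laterality mapping with latermap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latermap)
```

# The scientific problem

Handedness has both a behavioral signature (one hand performs skilled
grasping better than the other) and an anatomical one (the motor-hand
region of the precentral gyrus — the "knob" — differs between
hemispheres in size and tissue composition). `latermap` implements a
complete analysis chain linking the two on registered 3-D brain volumes:

1. **Functional laterality.** Per-subject activation volumes acquired
   during unilateral grasping are standardized, smoothed, and compared
   against their own left-right mirror image. A group t-map over the
   resulting difference volumes localizes activation that is reliably
   stronger in one hemisphere than at the mirrored location.
2. **Anatomical laterality.** Per-subject binary tracings of the
   motor-hand region are summed into a probabilistic atlas, thresholded
   at fractional overlap levels, and used to quantify grey- and
   white-matter composition per hemisphere, summarized as asymmetry
   quotients.
3. **Behavioral laterality.** Per-hand grasping error counts give a
   handedness index per subject; population bias, structure-behavior
   correlations, and a handedness-by-threshold interaction connect the
   three domains.

All inputs are assumed registered to one voxel grid with axis 1 running
left to right. No real scans ship with the package; a synthetic phantom
generator produces full cohorts with implanted, recoverable effects so
that every stage is testable end to end.

# The volume model

Volumes are dense 3-D arrays with millimetre voxel geometry
(`ScalarVolume`, `BrainMask`, `TissueLabels`). The left-right dimension
must contain an even number of voxels, which places the mid-sagittal
plane exactly between the two central columns. This makes `flipLR()` an
exact involution — applying it twice returns the input bit for bit — and
makes hemisphere membership unambiguous: columns `1..nx/2` are the left
hemisphere. Volumes in other orientations are reoriented at load from
their NIfTI header axis codes; flipping and hemisphere splitting are then
purely index-based, because registration to a common template is treated
as a preprocessing step outside the package's scope (the flip of an
already-registered image needs no re-registration).

# The flip-subtract activation analysis

For each subject the pipeline computes, in order:

1. `standardize()`: every voxel is divided by the mean activation over
   the brain mask, so the in-mask mean becomes exactly 1. This cancels
   global uptake and dose differences between subjects; the output is
   invariant to rescaling the input by any positive constant.
2. `smoothIsotropic()`: a separable Gaussian low-pass filter,
   parameterized by its full width at half maximum (default 6 mm on every
   axis — the conventional description of neuroimaging smoothing
   kernels; the per-axis standard deviation in voxels is
   `fwhm / (2 sqrt(2 log 2)) / voxelsize`). The kernel is truncated at
   four standard deviations and renormalized at the grid faces, so
   constant volumes are exact fixed points, the total mass of a
   compactly supported volume is conserved, and — because the
   renormalization is mirror-symmetric — left-right antisymmetry is
   preserved exactly.
3. `differenceVolume()`: `D = v - flipLR(v)`, exactly antisymmetric by
   construction. Positive values mark voxels more active than their
   mirror twin.
4. `alignHand()`: subjects who grasped with the right hand have their
   difference volume flipped so that every subject's contralateral
   hemisphere occupies the same side of the grid. Left-hand subjects are
   the reference orientation because they form the majority of the
   default cohort.
5. `groupTMap()`: the voxelwise one-sample t of the aligned differences
   against zero, `t = mean / (sd / sqrt(n))`, with `df = n - 1`. Voxels
   with zero between-subject sd (possible on synthetic data outside the
   brain) are set to t = 0 and flagged rather than propagating
   infinities.
6. `extractClusters()`: connected components of `{t >= threshold}`
   (26-neighborhood by default, the common choice for cluster-extent
   thresholding; 6 and 18 are available), discarding components smaller
   than a minimum physical extent. The default threshold t = 4.54 is the
   one-tailed p = 0.01 critical value at df = 3, and the default extent
   is 72 mm^3, converted to a voxel count by the current voxel volume and
   rounded up. Only positive clusters are extracted: the t-map is
   antisymmetric, so every cluster has a mirrored negative twin that
   would be redundant to report.

Reported coordinates follow the laterality convention: `x` is the signed
millimetre distance from the mid-sagittal plane, negative on the
canonical (contralateral) side; `y` and `z` are distances from the most
anterior and most superior in-mask voxels. A cluster is attributed to the
contralateral hemisphere exactly when its peak has `x < 0`.

## Peak instability at few degrees of freedom

With four subjects the voxelwise sd estimate has three degrees of
freedom, and the location of the maximum t inside a genuine activation
cluster is dominated by sampling noise in the denominator: across seeded
phantom replicates the peak-t voxel wanders up to tens of millimetres
from the implanted blob center, and an occasional noise cluster attains a
higher peak t than the activation cluster itself. Cluster records
therefore carry two locations: the peak-t voxel (the conventional table
entry) and the *effect peak* — the within-cluster maximum of the
subject-average difference volume, which the pipeline computes anyway.
The effect peak localizes the implanted activation to within one voxel in
every replicate we simulate, and it is the location used by the
package's parameter-recovery validation.

## Operating characteristics of the extent rule

The default threshold pair (t = 4.54, 72 mm^3) controls the *per-voxel*
one-tailed error at 1% but does not control the family-wise error of a
whole-brain search on smooth data: 6 mm smoothing leaves on the order of
a thousand independent resolution elements in the brain mask, and
72 mm^3 is only a third of one (6 mm)^3 resel, so dozens of noise-driven
clusters survive even when no activation is implanted. This is inherent
to the threshold definition — the t statistic is scale-free, so no noise
amplitude changes it — and users should treat the cluster table on
smoothed data as exploratory unless a stricter extent or a resampling
correction is applied. On unsmoothed data the same pair is conservative:
independent voxel noise essentially never forms a 9-voxel component at
p = 0.01, and the amplitude-zero phantom yields empty cluster tables.

# The probabilistic atlas

`sumTracings()` counts, per voxel, how many subjects' tracings contain
it; subjects whose tracing is empty in either hemisphere are excluded
with a warning (a bilateral atlas cannot use them — mirroring the
practice of dropping unreliable tracings). `thresholdAtlas()` keeps
voxels present in at least `minOverlapCount(n, fraction)` subjects:
the nearest integer to `fraction * n` with halves rounding up, floored at
one subject. Rounding to nearest is the unique rule consistent with
mapping 30/50/70% of 62 subjects to 19/31/43 (flooring would give 18,
ceiling 44). Object maps at rising fractions are nested level sets, so
their volumes are monotonically nonincreasing — a structural invariant
the tests assert on every simulated cohort. Hemisphere assignment of
object-map voxels is by grid side, not by which tracing component
generated them, since tracings are bilateral and hemispheres are
quantified separately.

# Tissue quantification and asymmetry quotients

`tissuePercentages()` divides the GM/WM/CSF voxel counts inside an
object map by the *full* map volume (including any unlabeled voxels), so
GM and WM percentages need not sum to 100 in general; when the map
contains only the two cortical compartments they sum to exactly 100 and
are perfectly anticorrelated across subjects — a closure property the
tests verify, and the mechanism behind strongly negative GM-WM
correlations in real cohorts.

The asymmetry quotient is the standard laterality quotient
`AQ = (R - L) / (0.5 (R + L))`, bounded in [-2, 2], positive rightward,
attaining a bound only when one side is zero. The handedness index from
per-hand error counts is `HI = (errR - errL) / (errR + errL)`, bounded in
[-1, 1]; because errors count failures, *negative* HI means better
right-hand performance. Subjects with equal errors (HI = 0) or no errors
are excluded from classification.

`bilateralVOI()` fuses a cluster with its mirror image into an exactly
symmetric volume of interest, so functional clusters can be quantified
per hemisphere on anatomical segmentations;
`voiStructureCorrelation()` then correlates per-subject tissue
composition inside the VOI with composition inside each atlas map.

# Behavioral statistics

The population bias test is the one-sample t of the HI values against
zero (delegated to `stats::t.test`); correlations are Pearson r with the
two-sided t-transform p (`stats::cor.test`). The handedness-by-threshold
analysis is a two-way mixed-design ANOVA — handedness group between
subjects, atlas threshold within — fit by `stats::aov` with an
`Error(subject/threshold)` stratum, reporting the classical univariate
interaction F with `df1 = T - 1` and `df2 = (T - 1)(N - G)` and no
sphericity correction. All three are cross-checked in the test suite
against independent hand-rolled implementations (explicit t and r
formulas, a direct sums-of-squares decomposition for the interaction F).

# The synthetic phantom

`simulateCohort()` generates, from one master seed:

- a left-right symmetric ellipsoidal **brain mask** (about a third of
  the default grid);
- per activation subject, a **volume** with baseline 1 inside the mask,
  a Gaussian blob of amplitude `activationAmplitude` (default 3) and
  width `blobSigmaMM` (default 6 mm) centred on the knob of the
  hemisphere contralateral to the assigned hand, and iid Gaussian noise
  (`noiseSD`, default 1);
- per anatomical subject, a bilateral **tracing** (ellipsoids of 8 mm
  radius at the knob centers, jittered uniformly within ±2 mm per axis
  and scaled by a factor in [0.85, 1.15], clipped to the brain mask) and
  a **segmentation** whose hemisphere-specific WM probabilities
  `wmBase (1 ± a/2)` implant a target WM asymmetry quotient `a` drawn
  per subject from a normal distribution (mean -0.2, SD 0.5 by default —
  a modest leftward population bias with realistic between-subject
  spread), CSF at 3%, and a deterministic GM-shell/WM-core pattern
  elsewhere with 10% of voxels swapped per subject to mimic
  segmentation variability;
- per subject, **grasping error counts** per hand, binomial with 60
  trials per hand and a logit-scale error probability shifted by
  `handednessEffect * a / 2` (base error rate 0.2, effect 1.5): a
  leftward WM asymmetry lowers the right-hand error rate, so right
  performers carry leftward anatomy, the direction the pipeline is meant
  to recover. The logistic link keeps probabilities valid at every
  effect size, which is why it was chosen over an additive model.

The default grid is 64 x 64 x 48 voxels at 2 mm — large enough that the
6 mm kernel, the 72 mm^3 extent rule and the atlas geometry behave as
they would on real data, small enough that a full 62-subject cohort
simulates in seconds. Cohort sizes default to 4 activation subjects
(three left-handed, one right-handed) and 62 anatomical subjects. Every
subject draws from an independent substream derived from the master
seed, so enlarging a cohort never perturbs existing subjects and any
cohort is exactly reproducible.

What the phantom does *not* emulate: anatomy (the brain is an
ellipsoid), scanner physics (no attenuation, point-spread or motion),
spatially correlated acquisition noise, registration error, or manual
tracing behavior beyond jitter and scale. Passing tests therefore
demonstrate that the *computational pipeline* recovers implanted effects
under controlled conditions — not that any particular real dataset would
yield the same statistics.

# Numerical choices and degenerate inputs

- Even-nx grids are enforced at construction; odd grids are rejected
  with an error naming the mid-sagittal convention rather than silently
  choosing a pivot column.
- Smoothing with a zero-width kernel returns its input unchanged;
  negative widths are errors.
- Zero-sd voxels in the t-map become t = 0 (flagged) instead of ±Inf.
- Empty object maps at high thresholds produce empty masks with a
  warning, not an error; empty maps passed to quantification are errors
  that name the offending hemisphere/threshold.
- Zero-variance inputs to correlation are flagged `NA` with a warning;
  zero-variance inputs to the t test are errors.
- The minimum extent in mm^3 converts to voxels by `ceiling`, so a
  cluster must fully reach the physical extent.
- AQ with `R + L = 0` and HI with no errors are undefined and rejected
  or excluded, respectively.

# Problem sizes used in validation

The package's own validation runs on the default 64 x 64 x 48 grid with
4-subject activation cohorts and 60-62-subject anatomical cohorts;
oracle cross-checks use 8^3-16^3 volumes where brute-force enumeration
is exact; null calibration of the bias test uses 10,000 simulated
cohorts of n = 70; the laterality-link check uses 50 seeded cohorts of
n = 60. These sizes were chosen so the full suite exercises every stage
at realistic scale while remaining quick to run.

# Known limitations

- The cluster-extent rule's family-wise error is uncontrolled on
  smoothed data (see above); no permutation or random-field correction
  is provided.
- The mixed ANOVA applies no sphericity correction, matching the
  classical univariate convention; with three within-subject levels and
  mild covariance heterogeneity this can be slightly liberal.
- Hemisphere attribution of clusters is by the sign of the reported x
  coordinate alone; a cluster straddling the midline is attributed by
  its peak.
- The phantom's behavioral link is generative and logistic; it is not a
  fitted model of any real cohort.
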