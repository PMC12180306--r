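---
title: "Localizing the seizure onset zone from resting-state fMRI components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the seizure onset zone from resting-state fMRI components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sozica)
```

## The model

`sozica` assumes the seizure onset zone (SOZ) leaves a detectable imprint
on interictal resting-state BOLD: a spatially focal, hemispherically
lateralized source with low-frequency power and occasional spike-like
(super-Gaussian) temporal surges, embedded among bilateral resting
networks, extracerebral artifacts, and scanner drift. Spatial ICA
decomposes each subject's preprocessed, template-normalized 4D series into
components; the epileptic component is identified not by any single
feature but by a conjunction of nine, thresholded against the cohort.

The decomposition is the linear mixture `X = A S`, with `X` the T×V
voxelwise-demeaned series, `S` spatial sources, and `A` variance-normalized
time courses. We fit it with the FastICA fixed point (logcosh contrast,
symmetric decorrelation) after PCA whitening to the requested model order.
Maps are converted to Z-scores using in-mask statistics — out-of-brain
voxels are standardized by the same statistics, because the
outside-to-inside ratio feature deliberately counts suprathreshold voxels
on both sides of the mask — and sign-flipped so the maximum-|Z| in-mask
voxel is positive, removing the sign indeterminacy of ICA.

## Features and their directions

Per component, five clustering levels are derived in fixed order:
significance clusters (contiguous regions of strictly more than 10 voxels
with Z strictly above 3.1; 26-connectivity by default, configurable to 6),
morphologically opened-then-closed clusters (ball of radius 2 voxels,
configurable to a per-slice disk), the main connected component containing
the component centre (the maximum-Z in-mask voxel, lexicographic
tie-break), the central local average (mean series over the 3×3×3
neighbourhood intersected with the mask; a radius-3 ball is available),
and the centre voxel's own series. The centre is defined on the raw Z-map,
independent of the masks; when opening deletes the centre voxel the
nearest surviving region is used, with a warning.

The nine features and their expected directions for the epileptic
component: outside-to-inside suprathreshold ratio (low — artifacts load
outside the parenchyma), dominant periodogram frequency of the central
local average (inside 0.01–0.1 Hz, inclusive; below is drift, above is
aliased physiology), lateralization index `1 − |r|` between mirror-paired
in-mask voxels (high), lateralization strength over non-mirrored
suprathreshold voxels (high), mean pairwise correlation of the main
cluster (low), unbiased variance of the distinct pairwise correlations
(high), mean centre-to-cluster correlation (low), central energy
`Σ x_c(t)²` (maximal), and the largest absolute excess kurtosis over
temporal ICA sources of the main cluster (maximal). Kurtosis uses plain
sample central moments, not a bias-corrected estimator. The pairwise
variance counts each unordered pair once. The lateralization index takes
an absolute value, so exactly anti-symmetric maps score 0, like symmetric
ones; we keep that behaviour as defined.

Mirroring operates about the mid-sagittal plane of the normalized grid:
the world `x = 0` plane mapped into voxel space, stored as a half-integer
voxel position so mirroring is an exact voxel bijection. On odd-width
axes the central column lies on the plane and belongs to neither
hemisphere. For non-standard grids the midline can be set explicitly.

## Classification

Cohort thresholds are `mean ± k·SD` of each gated feature over all
non-degenerate components of all subjects (degenerate components — those
without any surviving significance cluster — are excluded from the
statistics so they cannot drag the thresholds; this is configurable in
spirit but hard-wired here as the safer default). The offset points
toward each feature's expected tail ("strict"); a "lenient" mode offsets
away from it. `k = 1` by default. A subject with no component passing all
seven gates has `k` relaxed in 0.25 steps to 0, and the frequency-band
gate dropped last; every relaxation is recorded in the decision table.
Among candidates, central energy and maximum kurtosis are prioritized by
rank sum, ties going to the higher kurtosis and then the lower component
index; a lexicographic mode (energy, then kurtosis) is available. Exactly
one component is selected per localizable subject.

The SOZ is the main connected component (containing the centre) of the
selected component's opened-and-closed significance clusters. Against a
resection mask, concordance is `full` on any voxel overlap, `partial`
when the modal lobe label matches without overlap, `discordant`
otherwise; the Dice coefficient and overlap count are recorded. The
minimum-overlap rule (one voxel) is deliberate: no overlap threshold is
part of the method's definition.

## The synthetic cohorts

The generator emulates the statistical structure the classifier assumes,
at a desk scale chosen so a full eight-subject cohort runs in well under
a minute: a 40×48×40 voxel grid at 2 mm, 160 time points at TR = 3 s, an
ellipsoidal brain mask, and per subject four mirrored bilateral networks
(band-limited 0.015–0.075 Hz signals), two coherent rim artifacts
(loadings concentrated outside the brain with a weak bleed into its
boundary layer, dominant power above 0.1 Hz), a slow drift (0.005 Hz)
over a broad central profile, diffuse physiological noise (temporally
smoothed voxel-private fluctuations, SD 1.2), white noise (SD 1), and one
epileptic source: a unilateral inferior-lateral Gaussian blob (sigma 3
voxels, truncated at 2 sigma) whose signal mixes a sinusoid drawn from
0.02–0.04 Hz with a Poisson spike train (rate 0.03/frame, at least two
events) convolved with a canonical double-gamma hemodynamic response
(response peak near 6 s, undershoot near 16 s), in a 0.4/0.6 variance
ratio so the dominant frequency is the sinusoid's while the kurtosis
stays spike-driven. Within-blob correlation heterogeneity comes from
voxelwise jitter: each blob voxel carries private broadband fluctuations
weighted `U(0.6, 1.6)` relative to its shared loading, which spreads the
local correlations (high diversity, low clustering and centre strength)
while projecting almost entirely outside the low-frequency subspace the
decomposition retains, so the focal source stays one component.

Three construction rules matter for interpretability. Planted sources are
support-disjoint: compact sources are placed so centres stay outside each
other's support (the epileptic blob first, since its territory is the
most constrained; network mirrors are checked too), artifact patches skip
already-claimed voxels, and the drift profile is zeroed over every
compact support. Overlapping planted sources would be statistically
dependent, and no ICA could separate them even without noise — the
noiseless plant-and-recover tests (spatial correlation above 0.99) rely
on this. Second, the diffuse physiological noise is what keeps the
surplus model-order components diffuse: without it, the retained
dimensions beyond the true sources latch onto whatever localized variance
exists (the blob jitter) and fragment the focal source. Third, epileptic
sides alternate across subjects so cohorts are balanced.

What passing the planted-cohort tests does *not* show: real BOLD has
spatially correlated, temporally autocorrelated noise, imperfect
registration, and epileptic networks that are neither Gaussian blobs nor
support-disjoint from resting networks. The synthetic study validates the
pipeline's mechanics and the classifier's logic under its stated
assumptions, not clinical performance.

## Numerical choices

* **FastICA convergence.** The first fit starts from the whitened PCA
  basis (usually far closer to the fixed point than a random rotation,
  and empirically much less prone to stalling at saddles of the
  contrast); retries use seeded random rotations. The fixed point
  iterates until the worst per-component rotation delta stays below 1e-5
  for five consecutive iterations — the delta also dips below tolerance
  transiently while crossing saddles, and stopping at a single dip can
  leave a pair of sources mixed. Near-Gaussian subspaces (small-sample
  clusters, noise-only directions) have no identifiable fixed point and
  can cycle indefinitely; after bounded iterations the best iterate is
  accepted if its delta is below 0.05, the fit is otherwise retried, and
  as a last resort the best rotation seen is returned with a warning.
  The identifiable components settle early, so the features are
  insensitive to residual rotation within the Gaussian subspace. All of
  this is deterministic given the seed.
* **Subsampled unmixing.** For very wide data the unmixing rotation is
  estimated on a seeded random subsample of 30,000 voxels and the sources
  are then projected from the full data; the estimation error of a
  rotation from 30,000 samples is negligible at these model orders.
* **Temporal ICA order.** Within a cluster, `min(5, N, T−1)` sources are
  requested, reduced to the data rank with a warning (a perfectly
  coherent cluster has rank 1). Only the maximum-kurtosis source feeds
  the feature, so modest over-extraction is harmless.
* **Morphology.** Closing runs on a padded copy of the array: clipping
  the dilation at the array edge would lose mass and break the
  (infinite-background) closing semantics, including the idempotence of
  the open–close filter. A ball structuring element rounds cube corners;
  that is expected, not a defect.
* **Degenerate inputs.** Constant maps, constant hemisphere arrays, and
  constant cluster series raise errors at the operation level; the
  per-component feature extractor converts a degenerate lateralization
  index into `NA` (failing its gate) rather than aborting a subject, and
  a zero in-mask suprathreshold count maps the outside-to-inside ratio to
  `Inf`, an automatic rejection.
* **Ties.** Component centres break Z ties lexicographically; the
  nearest-region fallback prefers the larger region, then the lowest
  lexicographic seed voxel; selection ties go to higher kurtosis, then
  lower component index. All deterministic.

## Problem sizes

The acceptance study runs twenty seeded cohorts of eight subjects with
twenty components each at the default grid — the model order is scaled to
the synthetic source inventory, while the pipeline default stays at
thirty components, the standard order for full-resolution resting-state
data. The unit-test cohorts use a 34×40×34 grid, 100 time points, three
subjects and ten components; feature-oracle checks run on grids up to
10×9×8 with 24–64 time points.

## Known limitations

The threshold directions assume the epileptic component is an outlier in
a cohort dominated by non-epileptic components; in tiny cohorts (or a
single subject) the cohort statistics are unstable and the relaxation
ladder does most of the work. The strict threshold mode can be
unsatisfiable for skewed features (a one-SD offset below the mean of a
non-negative feature can be negative), which the ladder absorbs by
settling at a smaller `k`; this mirrors the method's behaviour rather
than papering over it. Anti-symmetric maps score as symmetric in the
lateralization index. Concordance uses the functional grid; mapping to a
higher-resolution structural space is upstream registration work, out of
scope here.
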