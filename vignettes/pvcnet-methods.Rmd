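---
title: "Partial volume correction and its downstream impact: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial volume correction and its downstream impact: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

PET scanners resolve structure at roughly 5–6 mm full-width-at-half-maximum
(FWHM), so the observed amyloid tracer image is well modelled as the true
activity distribution convolved with a 3D point-spread function (PSF), plus
noise. The resulting partial volume effect (PVE) mixes signal between a
region of interest and its neighbours, biasing regional quantification
(SUVR), the correlation networks built from regional values across
subjects, and any classifier trained on the images. `pvcnet` implements
three partial volume correction (PVC) algorithms and the full downstream
evaluation chain — quantification, group networks, graph metrics, and a
paired corrected-versus-uncorrected classification study — together with a
synthetic phantom cohort generator so that every stage is testable against
known ground truth without any external data.

Throughout, `i` denotes the observed image, `t` the estimate being
recovered, and `h` the PSF; all convolutions use a sampled Gaussian kernel,
truncated at 4 SD per axis, renormalized to sum to one, applied in the
frequency domain with reflective boundary padding (so total activity is
conserved and the conservation property is testable). The adjoint used in
gradients is the exact adjoint of the reflect-pad-then-convolve operator,
not a second forward convolution; for images that vanish near the grid
boundary (every bundled phantom) the operator is self-adjoint.

## The three correction algorithms

**Joint-entropy (JE) penalized deconvolution.** The corrected image
minimizes

    sum_x || i(x) - (t * h)(x) ||^2  +  w * JE(t, MR)

where `JE` is the joint entropy of the PET/MR intensity pair distribution,
estimated by a Parzen (Gaussian-kernel) density on a regular 64 x 64
intensity-bin grid with bandwidth equal to one bin width per axis.
Penalizing the joint entropy concentrates the joint PDF, favouring PET
estimates whose intensity classes follow the anatomy: a smooth image with
boundaries sharp where the MR has them. (The objective is sometimes printed
with the penalty as `+ sum p log p`, i.e. the negative entropy; minimizing
that form would *maximize* entropy and demonstrably degrades recovery with
increasing weight, so `pvcnet` uses the sign consistent with the method's
stated intent and behaviour.) Minimization is projected gradient descent
under a non-negativity constraint with a backtracking Armijo line search,
which guarantees a monotone non-increasing objective trace. The JE gradient
is computed analytically through the Parzen kernels (including the
chain-rule term from the explicit renormalization of the discrete density)
and is verified against central finite differences in the tests. The
intensity bin grid is frozen at the first iterate — spanning the observed
range widened by 50% — so the objective stays smooth as the estimate's
range grows during deconvolution.

*Choice of `je_weight`.* The weight is absent from the published objective.
On the bundled phantom (48^3 grid, 2 mm voxels, 90 regions, 6 mm FWHM,
noise SD 5% of baseline activity) a decade sweep gives, after 12
iterations:

| weight | voxel RMSE | region-mean RMSE |
|-------:|-----------:|-----------------:|
| 0 (pure LS) | 0.560 | 0.282 |
| 1e3    | 0.560 | 0.264 |
| 3e3    | 0.498 | 0.234 |
| 1e4    | 0.497 | 0.284 |
| 3e4    | 0.451 | 0.398 |
| uncorrected | 0.777 | 0.590 |

The default `je_weight = 3e3` is the joint sweet spot: best region-mean
recovery and near-best voxel recovery. All weights up to 3e4 improve both
criteria over the uncorrected image; iteration-wise region RMSE is monotone
decreasing at the study noise level even unregularized, so the weight is
not needed for stability, only for the anatomical prior's benefit.

**Modified Van Cittert (LSPVC).** Steepest descent on the least-squares
criterion with the fixed iteration

    t_0 = i;   t_{k+1} = t_k + alpha * (h * (i - h * t_k)),

step length `alpha = 1.5`, terminated when the relative update
`||t_{k+1} - t_k|| / ||i||` drops below 0.01. A divergence guard (not part
of the published scheme, which assumes a stable step) stops the iteration
if the LS objective rises for five consecutive steps; it never triggers on
converging runs.

**Geometric transfer matrix (GTM).** Region-level rather than image-level:
each region's indicator is convolved with the PSF to give its regional
spread function (RSF), and the transfer matrix entry
`omega[j, i] = (1/n_vox(j)) * sum_{r in ROI_j} RSF_i(r)` (integration is
voxel summation, the only discretization available on an image grid)
relates true to observed regional means through `t = Omega T`. Solving the
dense linear system recovers the true means. On a noiseless phantom blurred
with the exact PSF this is exact to solver precision, which the test suite
uses as its strongest oracle. An ill-conditioned `Omega` (condition number
above 1e8, e.g. regions much smaller than the PSF) is refused with an
explanatory error.

## Quantification

Regional means are the standard mask-weighted mean `sum(w p) / sum(w)` over
each parcel. (The published matrix formula carries an extra `1/k_s` factor
that would shrink every mean by the region's voxel count; under that
literal reading a constant image would not reproduce its own constant, so
the factor is treated as typographical.) SUVR volumes divide by the mean
over a reference region — in the phantom, the parcel with the lowest
z-centroid stands in for cerebellar gray matter. Regional summaries use the
10% interquartile mean

    IQM = (9/10)/n * sum_{i = floor(0.05 n + 1)}^{ceil(0.95 n)} x_(i)

implemented verbatim as the default (`"as_printed"`). Note the printed
normalization is not mean-preserving — on constant input `c` it returns
`c * 0.9 * kept/n`, about `0.81 c` for large n; a `"mean_preserving"` mode
dividing by the retained count is provided, and both behaviours are
asserted in the tests. Group tables report the across-subject mean, sample
SD (n − 1 denominator; the published work does not state its convention)
and the coefficient of variation SD/mean per (region, group, method).

## Group networks and graph metrics

Networks are built per group in the fixed published order: Pearson
correlation of region rows across subjects; negative entries replaced by
zero; column z-scoring (mean 0, sample SD 1 per column); division by the
maximum connection value (shared across the group networks of one
condition, for inter-group comparability); proportional thresholding that
keeps the largest `floor(p m(m-1)/2)` off-diagonal weights (p = 0.1 by
default, stable tie-break by index order). Column z-scoring destroys
symmetry, so the matrix is re-symmetrized by averaging with its transpose
before thresholding; all downstream metrics assume undirected graphs.

A per-network proportional threshold fixes every group's density at `p`, so
it cannot produce between-group density differences. For trend analyses the
package therefore also provides a fixed-cutoff threshold
(`threshold_at()`, with `pooled_cutoff()` choosing the value that retains a
fraction `p` of the pooled weights across all group networks): applied
uniformly, it preserves the between-group differences in correlation
strength, and on synthetic cohorts whose within-block correlation decreases
across groups it yields monotonically decreasing density, global efficiency
and clustering — the qualitative disease-progression trend.

Metrics follow the standard definitions: binarized node degree and density
`d = 2K/(N^2 - N)` with N taken from the matrix; global efficiency as the
mean inverse binary shortest-path length (disconnected pairs contribute 0);
clustering as the weighted-undirected geometric-mean-of-triangles form on
max-normalized weights (a binary variant is available; nodes of degree < 2
contribute 0); betweenness centrality normalized by `(N-1)(N-2)/2`; and
modularity

    Q = sum_i [ p_i / P - (d_i / (2P))^2 ]

over modules (within-module edges `p_i`, module degree sums `d_i`, total
edges `P`) on the binarized graph. The modularity maximizer is greedy and
seeded: node-move passes (including moves into a fresh singleton
community), best-pair community merges, and random initial partitions are
alternated over several restarts, and the best partition wins. Dense little
graphs have shallow local optima, so small graphs get extra restarts; the
tests verify the maximizer against exhaustive partition enumeration on
graphs of up to 8 nodes.

## Classification study

The paired design asks whether correction makes groups easier to tell
apart: for each repetition one stratified 10-fold assignment is drawn and
applied identically to the uncorrected and corrected feature sets, the
classifier is fit with identical hyperparameters on both arms, and the
per-repetition error rates and their difference are recorded; ROC curves
pool decision scores across repetitions. Stratification (rather than fully
random folds) guarantees both classes in every training split at realistic
group sizes.

The corrected arm is the joint-entropy method's output throughout — the
study compares each classifier on uncorrected versus JE-corrected data, so
one correction method is evaluated end to end (GTM and Van Cittert serve as
quantification comparators).

Three classifiers are provided. SVM (linear kernel, C = 1) consumes HOG
descriptors — 2D histogram-of-oriented-gradients features (9 unsigned
orientation bins, 8-voxel cells, L2 block normalization with a zero guard
so uniform slices give zero descriptors) computed on 9 evenly spaced axial
slices and concatenated; HOG is a 2D descriptor, so slices are the natural
3D extension. LDA consumes the same HOG descriptors, reduced per training
fold by PCA (at most 40 components, never more than the training size
allows) so its pooled covariance stays estimable; constant training columns
are dropped per fold. Feeding LDA regional mean vectors instead is
supported but deliberately not the default: the blur acts on regional means
as an invertible linear map plus small noise, and a linear classifier is
essentially indifferent to invertible linear transformations of its
features, so region-mean LDA cannot register the benefit of correction
even when correction demonstrably improves the features' accuracy — the
effect PVC has on classification lives in image-level descriptors. MSD —
matched subspace detection — treats each
subject's regional vector as a signal on the group network graph: for each
class, the training fold's thresholded network gives a Laplacian `L = D - W`
whose first k eigenvectors (ascending eigenvalue, the low-frequency end)
span the class subspace, with k chosen as the smallest dimension capturing
90% of the training class's centered signal energy, capped at m/4. The
two-class rule assigns a test signal to the class whose subspace captures
more of the signal's energy around that class's training mean —
equivalently the smaller orthogonal residual `||(I - U U')(x - mu_c)||^2`.
A raw energy-fraction rule without the class mean would be blind to mean
shifts entirely (any constant offset lies in the span of every connected
graph's lowest Laplacian eigenvector, and a fraction is scale-invariant),
so the affine residual form is the only two-class version of the detector
that can use the class structure the study manipulates. `msd_statistic()`
itself exposes the classical energy fraction `||U U' x||^2 / ||x||^2`.

## The phantom generator: what it emulates and what it does not

The generator stands in for a co-registered, parcellated multi-group
amyloid study. Anatomy is geometric — an outer ellipsoid brain with a
gray-matter shell, white-matter core and central CSF ventricle — because
only the statistical structure matters downstream; parcels are nearest-seed
(Voronoi) cells within the brain mask with reproducibly sampled seeds, 90
regions by default, labelled in order of decreasing gray-matter share so
that low labels are cortical (amyloid elevation targets the cortex, and a
spatially consistent target keeps phantom cohorts comparable across
seeds). Per-group region activities are multivariate normal,
clipped at zero, with mean `base_activity = 6` (arbitrary tracer units), a
10% per-region coefficient of variation across subjects, and a block
(community) correlation structure: 6 equal blocks over the
gray-matter-like regions, within-block correlation 0.8 / 0.6 / 0.4 / 0.2
along the NC → EMCI → LMCI → AD progression, 0 between blocks. This
decreasing coupling gives the network metrics their expected downward
trend. The most cortical quarter of the regions forms an "amyloid-prone"
subset whose mean activity is elevated by 0 / 15% / 30% / 45% along the
progression; the 15% step of the hardest (NC vs EMCI) contrast was chosen
so that baseline classification errors land in the 15–35% regime reported
for real hardest-contrast studies — with much smaller steps every
classifier sits at chance and no correction effect is measurable, with
much larger ones both arms are perfect. The least cortical fifth of the
regions carries white-matter-like non-specific tracer binding: elevated
mean (1.5 × baseline), larger inter-subject variability (25% CV), and its
own strong correlation block (r = 0.9) identical across groups — a
disease-unrelated nuisance that the blur mixes into cortical measurements,
mirroring the non-specific white-matter signal that partial volume
contributions inject into cortical amyloid quantification in real scans.
Acquisition is PSF blur (6 mm FWHM default — a configurable stand-in,
since the effective post-harmonization scanner resolution is not
published) plus additive Gaussian noise (SD 5% of baseline activity)
clipped at zero.

The phantom deliberately omits: realistic neuroanatomy, within-region
activity texture, MR pulse-sequence or sinogram-level physics, Poisson
count noise, motion, attenuation, registration and segmentation error.
Passing tests therefore demonstrate the correctness of the algorithms and
the direction of PVC's downstream effects under the modelled physics — not
performance on clinical data, where registration/segmentation noise is a
known additional cost of PVC.

## Numerical choices and degenerate inputs

- PSF kernels with FWHM 0 are the identity; kernel support is capped at the
  grid extent so reflective padding stays defined.
- The Parzen density is renormalized to integrate to exactly 1 on the bin
  grid (truncated kernel tails would otherwise leak mass); entropy terms
  use the convention `0 log 0 = 0`.
- Armijo parameters: initial step 1, backtrack factor 0.5,
  sufficient-decrease constant 1e-4 (standard values; the published work
  names the rule but not the constants).
- `gtm_correct` refuses solutions whose relative residual exceeds 1e-8;
  `gtm_matrix` refuses condition numbers above 1e8.
- Proportional thresholding breaks ties by index order, so results are
  deterministic; `p = 0` yields the empty network, `p = 1` keeps every
  off-diagonal weight.
- Zero-variance regions (constant across subjects) and constant z-score
  columns are errors naming the offending region, not silent drops.
- All randomness flows from explicit integer seeds through per-stage
  derived seeds; rerunning a pipeline configuration reproduces every TSV
  byte for byte.

## Problem sizes used by the test suite

The bundled study conditions are a 48^3 grid (2 mm voxels), 90 regions and
20 subjects per group. The test suite exercises the same conditions at
sizes chosen for quick iteration: recovery-ordering checks use the
48^3/90-region phantom with a subset of subjects per group; the
classification direction check uses a 32^3 grid with the bundled cohort
size (20 subjects per group) in the two hardest groups and 20
cross-validation repetitions — a regime where the baseline (uncorrected)
error rates land in the 15–35% band reported for hard clinical contrasts
and a correction effect is measurable (with many more subjects the phantom
groups become nearly separable in both arms and the paired differences
collapse to zero); exhaustive modularity enumeration is limited to graphs of at
most 8 nodes (4140 partitions). The acceptance script regenerates
everything it reports from scratch at run time.

## Known limitations

- The JE objective is non-convex; the optimizer guarantees monotone descent
  to a stationary point, not a global optimum.
- GTM's exactness assumes the parcellation matches the true activity
  compartments and the PSF is known; mismatch turns it into a biased
  estimator with no warning beyond the condition-number check.
- The fixed-cutoff network variant preserves group density differences but
  makes the retained edge count depend on the pooled weight distribution;
  the per-network proportional variant fixes the edge count but equalizes
  density across groups. Both are provided because they answer different
  questions.
- MSD assumes class-specific smoothness of signals on class graphs; with
  very few training subjects the network estimate (and hence the subspace)
  is noisy, and k falls back towards small dimensions.
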