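# pvcnet

Partial volume correction (PVC) for amyloid PET, and its downstream impact
on regional quantification, group-level brain networks and classification.

## The problem

PET scanners blur the true tracer distribution with a point-spread function
(PSF) of roughly 5–6 mm FWHM. The resulting *partial volume effect* mixes
signal between neighbouring structures, biasing regional SUVR values, the
correlation networks built from them across subjects, and classifiers
trained on the images. Whether and how to correct for it is a live question
in quantitative amyloid imaging. `pvcnet` is for researchers who want to
study that question under controlled conditions: it implements the three
standard correction algorithms and the complete downstream evaluation
chain, plus a synthetic phantom cohort generator with known ground truth,
so every claim can be tested without any clinical data.

## What is implemented

**Correction.** Modelling the observed image as `i = t * h + noise`:

- *Joint-entropy (JE) penalized deconvolution* — minimizes
  `sum_x ||i - t*h||^2 + w · JE(t, MR)`, where `JE` is the joint entropy of
  the PET/MR intensity pair distribution (Parzen estimate on a 64×64 bin
  grid). Penalizing JE favours PET estimates whose intensity classes follow
  the anatomy. Projected gradient descent with non-negativity and an Armijo
  line search; analytic JE gradient, verified against finite differences.
- *Modified Van Cittert iteration* (LSPVC) —
  `t_{k+1} = t_k + 1.5 · (h * (i - h * t_k))`, stopped when the relative
  update falls below 0.01.
- *Geometric transfer matrix* (GTM) — region-level correction: regional
  spread functions `RSF_i = indicator(D_i) * h` give the transfer matrix
  `omega_ij = (1/n_vox(j)) sum_{ROI_j} RSF_i`, and solving `t = Omega T`
  recovers true regional means. Exact on noiseless phantoms blurred with
  the known PSF.

**Quantification.** Mask-weighted regional means, SUVR normalization by a
reference region, robust 10% interquartile regional means
`(9/10)/n · sum_{floor(0.05n+1)}^{ceil(0.95n)} x_(i)`, and per-group
mean ± SD (CoV) tables.

**Networks.** Group networks in the fixed order Pearson correlation →
negative clipping → column z-scoring → global-max normalization →
proportional threshold (p = 0.1); graph metrics: density `2K/(N²−N)`,
global efficiency, weighted clustering, betweenness centrality, and
modularity `Q = sum_i [p_i/P − (d_i/2P)²]` with a seeded greedy maximizer
that matches exhaustive enumeration on small graphs.

**Classification.** Paired corrected-vs-uncorrected studies under repeated
stratified 10-fold cross-validation with identical folds and
hyperparameters in both arms: linear SVM and LDA on HOG slice descriptors
(LDA with a per-fold PCA reduction), and graph-Laplacian matched subspace
detection (MSD) on regional mean vectors, with ROC curves from pooled
decision scores.

**Phantoms.** Brain-shaped geometric phantoms (GM shell / WM core / CSF
ventricle), Voronoi parcels (90 regions by default), per-group multivariate
activities with block correlation structure whose strength decreases along
the NC → EMCI → LMCI → AD progression, PSF blur and additive noise — all
seeded and reproducible.

## Worked example

```r
library(pvcnet)

# a small two-group phantom study
spec <- cohort_spec(groups = c(NC = 4, EMCI = 4), seed = 1)
parc <- build_parcellation(c(32, 32, 32), spacing = c(2, 2, 2),
                           n_regions = 90, seed = 1)
acts <- sample_cohort_activities(spec)
psf  <- psf_model(6)                      # 6 mm FWHM scanner

# render one subject and simulate acquisition
rs  <- render_subject(parc, acts$NC$values[, 1])
obs <- simulate_acquisition(rs$true_pet, psf, noise_sd = 0.3, seed = 2)

# correct it three ways
je  <- je_deconvolve(obs, rs$mr, psf)     # anatomy-guided deconvolution
vc  <- vc_deconvolve(obs, psf)            # Van Cittert
gtm <- gtm_matrix(parc, psf)              # region-level transfer matrix
m_obs <- region_mean_matrix(list(obs), parc)$values[, 1]
m_gtm <- gtm_correct(m_obs, gtm)

# how close is each to the generator's ground truth?
truth <- acts$NC$values[, 1]
rmse <- function(m) sqrt(mean((m - truth)^2))
m_je <- region_mean_matrix(list(je$corrected), parc)$values[, 1]
m_vc <- region_mean_matrix(list(vc), parc)$values[, 1]
round(c(uncorrected = rmse(m_obs), VC = rmse(m_vc),
        JE = rmse(m_je), GTM = rmse(m_gtm)), 4)
#> uncorrected          VC          JE         GTM
#>      1.0070      0.5801      0.5263      0.1117
```

The printed numbers are region-mean RMSEs against the known ground-truth
activities: the observed (blurred + noisy) image misses the true regional
means by ~1.0 activity units on average; both image-domain deconvolutions
roughly halve that error, and GTM — which uses the exact parcellation and
PSF — nearly eliminates it, leaving only the noise floor. This ordering
(GTM < JE < uncorrected) is the package's core recovery property and is
asserted by the test suite.

The full study — four groups, all corrections, SUVR tables, network metric
panels pre/post correction, betweenness rankings and the paired
classification report — runs from one configuration:

```r
cfg <- pipeline_config(out_dir = "demo_run", seed = 7)
run_pipeline(cfg)   # writes TSV reports + manifest under demo_run/
```

A thin command-line wrapper with subcommands
(`phantom|pvc|quantify|network|classify|run-all`) is installed at
`inst/cli/pvcnet`.

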