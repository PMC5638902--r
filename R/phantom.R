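#' Build a brain-shaped synthetic parcellation
#'
#' Constructs a geometric brain phantom on a regular grid — an outer
#' ellipsoid with a gray-matter shell, a white-matter core and a central
#' CSF "ventricle" — and subdivides the brain mask into `n_regions`
#' nearest-seed (Voronoi) parcels with reproducibly sampled seed voxels.
#' Only the statistical structure of the parcellation matters downstream,
#' so no atlas data are required.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel size in mm (length 1 or 3).
#' @param n_regions number of parcels (>= 1).
#' @param seed integer seed controlling parcel seed placement.
#' @return Object of class `parcellation` with elements `labels` (3D integer
#'   array, 0 = background), `tissue` (3D integer array: 0 background, 1 GM,
#'   2 WM, 3 CSF), `regions` (data.frame with columns `label`, `name`),
#'   `spacing`.
#' @export
build_parcellation <- function(shape, spacing = c(2, 2, 2), n_regions = 90,
                               seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("build_parcellation: shape must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("build_parcellation: spacing must be positive")
  if (n_regions < 1L) stop("build_parcellation: n_regions must be >= 1")

  # voxel centre coordinates in units of half-extent, centred on the grid
  cc <- lapply(1:3, function(a) {
    x <- (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a]
    x / (shape[a] * spacing[a] / 2)
  })
  gx <- array(rep(cc[[1]], times = shape[2] * shape[3]), shape)
  gy <- array(rep(rep(cc[[2]], each = shape[1]), times = shape[3]), shape)
  gz <- array(rep(cc[[3]], each = shape[1] * shape[2]), shape)

  # nested ellipsoids (unit = half grid extent per axis)
  r2 <- function(sx, sy, sz) (gx / sx)^2 + (gy / sy)^2 + (gz / sz)^2
  brain <- r2(0.90, 0.90, 0.85) <= 1
  wm    <- brain & r2(0.55, 0.55, 0.50) <= 1
  csf   <- brain & r2(0.18, 0.18, 0.16) <= 1
  tissue <- array(0L, shape)
  tissue[brain] <- 1L          # GM shell
  tissue[wm] <- 2L
  tissue[csf] <- 3L

  nb <- sum(brain)
  if (nb < n_regions)
    stop("build_parcellation: n_regions (", n_regions,
         ") exceeds brain-mask voxel count (", nb, ")")

  brain_idx <- which(brain)
  seeds <- with_seed(seed, sort(sample(brain_idx, n_regions)))
  # physical coordinates of all brain voxels and seeds
  coord <- function(idx) {
    a <- arrayInd(idx, shape)
    sweep(a, 2, spacing, `*`)
  }
  bc <- coord(brain_idx)
  sc <- coord(seeds)
  # nearest seed assignment, ties broken by lower seed label
  lab <- integer(nb)
  best <- rep(Inf, nb)
  for (s in seq_len(n_regions)) {
    d2 <- (bc[, 1] - sc[s, 1])^2 + (bc[, 2] - sc[s, 2])^2 +
      (bc[, 3] - sc[s, 3])^2
    upd <- d2 < best
    lab[upd] <- s
    best[upd] <- d2[upd]
  }
  # relabel parcels by decreasing gray-matter share so that low labels are
  # cortical: group-level activity elevations applied to the first labels
  # (the amyloid-prone subset) then consistently target the GM shell
  gm_frac <- vapply(seq_len(n_regions), function(s) {
    ix <- lab == s
    mean(tissue[brain_idx[ix]] == 1L)
  }, numeric(1))
  ord <- order(-gm_frac, seq_len(n_regions))
  relab <- integer(n_regions)
  relab[ord] <- seq_len(n_regions)
  lab <- relab[lab]
  labels <- array(0L, shape)
  labels[brain_idx] <- lab
  regions <- data.frame(label = seq_len(n_regions),
                        name = sprintf("region_%03d", seq_len(n_regions)),
                        stringsAsFactors = FALSE)
  structure(list(labels = labels, tissue = tissue, regions = regions,
                 spacing = spacing),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s voxels, %d regions, %d brain voxels\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$regions),
              sum(x$labels > 0)))
  invisible(x)
}

#' Pick the reference region of a parcellation
#'
#' Returns the label of the region with the lowest z-centroid, the phantom's
#' stand-in for cerebellar gray matter used as the SUVR reference.
#'
#' @param parcellation a [build_parcellation()] result.
#' @return Integer region label.
#' @export
reference_region <- function(parcellation) {
  lab <- parcellation$labels
  idx <- which(lab > 0)
  z <- arrayInd(idx, dim(lab))[, 3]
  cz <- tapply(z, lab[idx], mean)
  as.integer(names(cz)[which.min(cz)])
}

#' Block (community) correlation matrix
#'
#' Builds an m x m correlation matrix with `n_blocks` contiguous equal-size
#' blocks, within-block correlation `within`, and `between` elsewhere.
#'
#' @param m number of regions.
#' @param n_blocks number of blocks.
#' @param within within-block correlation in `[0, 1)`.
#' @param between between-block correlation (default 0).
#' @return m x m correlation matrix; attribute `"block"` carries the block
#'   assignment.
#' @export
block_correlation <- function(m, n_blocks, within, between = 0) {
  blk <- rep(seq_len(n_blocks), length.out = m)
  blk <- sort(blk)
  R <- matrix(between, m, m)
  same <- outer(blk, blk, `==`)
  R[same] <- within
  diag(R) <- 1
  attr(R, "block") <- blk
  R
}

#' Cohort specification for the synthetic phantom study
#'
#' Bundles the study conditions the generator emulates: four diagnostic
#' groups whose within-block correlation strength decreases along the
#' NC -> EMCI -> LMCI -> AD progression, per-group region mean activities
#' with a group-dependent cortical uplift, a high-variance white-matter
#' non-specific-binding component that does not track disease stage, and
#' post-blur additive Gaussian noise.
#'
#' Region labels are assumed ordered by decreasing gray-matter share (as
#' [build_parcellation()] produces): the first `amyloid_frac` fraction of
#' labels is the cortical amyloid-prone subset receiving the group uplift,
#' and the last `wm_frac` fraction is the white-matter-like subset carrying
#' non-specific binding — elevated mean, larger inter-subject variance, and
#' its own strong correlation block identical across groups. Blur mixes
#' this disease-unrelated component into cortical measurements; its removal
#' is one of the things partial volume correction contributes.
#'
#' @param n_regions regions per subject (default 90).
#' @param groups named integer vector of subjects per group.
#' @param n_blocks number of correlation communities among the
#'   gray-matter-like regions (default 6).
#' @param within_r per-group within-block correlation, decreasing NC -> AD.
#' @param between_r between-block correlation (default 0).
#' @param base_activity baseline region activity (arbitrary tracer units).
#' @param uplift per-group fractional activity elevation applied to the
#'   amyloid-prone region subset.
#' @param amyloid_frac fraction of regions forming the elevated subset.
#' @param activity_cv coefficient of variation of per-subject region
#'   activities around the group mean (default 0.10).
#' @param wm_frac fraction of regions treated as white-matter-like
#'   (default 0.2; 0 disables the non-specific-binding component).
#' @param wm_mean_factor white-matter mean activity relative to
#'   `base_activity` (default 1.5).
#' @param wm_cv coefficient of variation of the white-matter component
#'   (default 0.25).
#' @param wm_r within-white-matter correlation, identical across groups
#'   (default 0.9).
#' @param noise_sd additive Gaussian noise SD on the observed image, as an
#'   absolute activity value (default 5% of `base_activity`).
#' @param fwhm_mm acquisition PSF FWHM in mm (default 6).
#' @param seed integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 90,
                        groups = c(NC = 20, EMCI = 20, LMCI = 20, AD = 20),
                        n_blocks = 6,
                        within_r = c(NC = 0.8, EMCI = 0.6, LMCI = 0.4,
                                     AD = 0.2),
                        between_r = 0,
                        base_activity = 6,
                        uplift = c(NC = 0, EMCI = 0.15, LMCI = 0.30,
                                   AD = 0.45),
                        amyloid_frac = 0.25,
                        activity_cv = 0.10,
                        wm_frac = 0.2,
                        wm_mean_factor = 1.5,
                        wm_cv = 0.25,
                        wm_r = 0.9,
                        noise_sd = 0.05 * base_activity,
                        fwhm_mm = 6,
                        seed = 1) {
  if (any(groups < 2)) stop("cohort_spec: subject counts must be >= 2")
  # allow group subsets of the default four-stage progression
  if (!is.null(names(within_r)) && all(names(groups) %in% names(within_r)))
    within_r <- within_r[names(groups)]
  if (!is.null(names(uplift)) && all(names(groups) %in% names(uplift)))
    uplift <- uplift[names(groups)]
  if (length(within_r) != length(groups) || length(uplift) != length(groups))
    stop("cohort_spec: within_r and uplift must match groups in length")
  if (noise_sd < 0) stop("cohort_spec: noise_sd must be >= 0")
  n_wm <- round(wm_frac * n_regions)
  n_gm <- n_regions - n_wm
  n_amy <- max(1L, round(amyloid_frac * n_regions))
  if (n_amy > n_gm)
    stop("cohort_spec: amyloid_frac and wm_frac overlap")
  gn <- names(groups)
  amy <- seq_len(n_amy)                     # most cortical labels
  wm <- if (n_wm > 0) (n_gm + 1):n_regions else integer(0)
  region_means <- sapply(gn, function(g) {
    mu <- rep(base_activity, n_regions)
    mu[amy] <- mu[amy] * (1 + uplift[[g]])
    mu[wm] <- base_activity * wm_mean_factor
    mu
  })
  region_cv <- rep(activity_cv, n_regions)
  region_cv[wm] <- wm_cv
  correlation_model <- lapply(gn, function(g) {
    Rgm <- block_correlation(n_gm, n_blocks, within_r[[g]], between_r)
    R <- diag(n_regions)
    R[seq_len(n_gm), seq_len(n_gm)] <- Rgm
    if (n_wm > 0) {
      R[wm, wm] <- wm_r
      diag(R) <- 1
    }
    attr(R, "block") <- c(attr(Rgm, "block"),
                          rep(n_blocks + 1L, n_wm))
    R
  })
  names(correlation_model) <- gn
  structure(list(n_regions = n_regions, groups = groups,
                 region_means = region_means,
                 region_cv = region_cv,
                 correlation_model = correlation_model,
                 activity_cv = activity_cv, noise_sd = noise_sd,
                 fwhm_mm = fwhm_mm, amyloid_regions = amy,
                 wm_regions = wm, seed = seed),
            class = "cohort_spec")
}

check_correlation <- function(R, group) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    stop("cohort correlation matrix for group '", group, "' is not symmetric")
  if (any(abs(diag(R) - 1) > 1e-10))
    stop("cohort correlation matrix for group '", group,
         "' does not have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cohort correlation matrix for group '", group,
         "' is not positive semi-definite")
  invisible(TRUE)
}

#' Sample ground-truth region activities for a cohort
#'
#' Draws, for each group, an (regions x subjects) matrix of true region
#' activities from a multivariate normal with the group's mean vector and
#' block correlation structure, clipped at zero.
#'
#' @param spec a [cohort_spec()].
#' @return Named list of [intensity_matrix()] objects, one per group.
#' @export
sample_cohort_activities <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gn <- names(spec$groups)
  out <- vector("list", length(gn))
  names(out) <- gn
  for (g in gn) {
    R <- spec$correlation_model[[g]]
    check_correlation(R, g)
    mu <- spec$region_means[, g]
    sdv <- spec$region_cv * mu
    Sigma <- (sdv %o% sdv) * R
    n <- spec$groups[[g]]
    X <- with_seed(derive_seed(spec$seed, paste0("activities.", g)),
                   MASS::mvrnorm(n, mu = mu, Sigma = Sigma))
    X <- pmax(t(X), 0)           # regions x subjects
    out[[g]] <- intensity_matrix(X,
                                 region_labels = seq_len(spec$n_regions),
                                 subject_ids = sprintf("%s_%02d", g,
                                                       seq_len(n)),
                                 group = g)
  }
  out
}

#' Render one subject's true PET and MR volumes
#'
#' The true tracer image is piecewise constant over parcels (each region's
#' voxels take its assigned activity; background is zero). The MR-like
#' anatomical image is piecewise constant over tissue classes.
#'
#' @param parcellation a [build_parcellation()] result.
#' @param activities numeric vector of per-region activities (length =
#'   number of regions).
#' @param mr_tissue_values named numeric: intensities for `gm`, `wm`, `csf`,
#'   `bg`.
#' @return List with `true_pet` and `mr`, both [vol_image()].
#' @export
render_subject <- function(parcellation, activities,
                           mr_tissue_values = c(gm = 100, wm = 70, csf = 25,
                                                bg = 0)) {
  m <- nrow(parcellation$regions)
  if (length(activities) != m)
    stop("render_subject: expected ", m, " activities, got ",
         length(activities))
  lut <- c(0, as.numeric(activities))
  pet <- array(lut[parcellation$labels + 1L], dim(parcellation$labels))
  tlut <- c(mr_tissue_values[["bg"]], mr_tissue_values[["gm"]],
            mr_tissue_values[["wm"]], mr_tissue_values[["csf"]])
  mr <- array(tlut[parcellation$tissue + 1L], dim(parcellation$tissue))
  list(true_pet = vol_image(pet, parcellation$spacing),
       mr = vol_image(mr, parcellation$spacing))
}

#' Simulate PET acquisition: PSF blur plus additive noise
#'
#' Models the scanner's finite resolution as convolution of the true image
#' with a spatially invariant Gaussian PSF, followed by additive Gaussian
#' noise, clipped at zero.
#'
#' @param true_pet a [vol_image()] of true activity.
#' @param psf a [psf_model()].
#' @param noise_sd additive noise standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @return Observed [vol_image()].
#' @export
simulate_acquisition <- function(true_pet, psf, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("simulate_acquisition: noise_sd must be >= 0")
  obs <- convolve_psf(true_pet, psf)
  v <- obs$values
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
  }
  vol_image(pmax(v, 0), true_pet$spacing, true_pet$origin)
}

#' Generate a full phantom cohort
#'
#' Convenience wrapper tying the generator together: builds the
#' parcellation, samples per-group ground-truth activities, renders each
#' subject and simulates acquisition.
#'
#' @param spec a [cohort_spec()].
#' @param shape grid dimensions (default `c(48, 48, 48)`).
#' @param spacing voxel size in mm (default 2).
#' @return List with `parcellation`, `spec`, `activities` (list of
#'   [intensity_matrix()] per group), `mr` (shared anatomical volume),
#'   `subjects` (per group, list of per-subject lists with `true_pet` and
#'   `observed`).
#' @export
generate_cohort <- function(spec, shape = c(48, 48, 48), spacing = c(2, 2, 2)) {
  parc <- build_parcellation(shape, spacing, spec$n_regions,
                             seed = derive_seed(spec$seed, "parcellation"))
  acts <- sample_cohort_activities(spec)
  psf <- psf_model(spec$fwhm_mm)
  mr <- NULL
  subjects <- lapply(names(spec$groups), function(g) {
    A <- acts[[g]]$values
    lapply(seq_len(ncol(A)), function(j) {
      rs <- render_subject(parc, A[, j])
      if (is.null(mr)) mr <<- rs$mr
      obs <- simulate_acquisition(rs$true_pet, psf, spec$noise_sd,
                                  seed = derive_seed(spec$seed,
                                                     paste0("noise.", g, ".", j)))
      list(true_pet = rs$true_pet, observed = obs)
    })
  })
  names(subjects) <- names(spec$groups)
  list(parcellation = parc, spec = spec, activities = acts, mr = mr,
       subjects = subjects)
}

#' Write a parcellation to disk
#'
#' Writes the integer label volume as NIfTI and the region table as TSV.
#'
#' @param parcellation a [build_parcellation()] result.
#' @param nii_path output NIfTI path for the labels.
#' @param tsv_path output TSV path for the region table (columns `label`,
#'   `name`).
#' @return Invisibly, the two paths.
#' @export
write_parcellation <- function(parcellation, nii_path, tsv_path) {
  write_volume(vol_image(parcellation$labels, parcellation$spacing),
               nii_path, datatype = "int32")
  utils::write.table(parcellation$regions, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nii_path, tsv_path))
}
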