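#' Volumetric image
#'
#' A 3D scalar grid with per-axis voxel spacing in millimetres. This is the
#' carrier type for PET, MR, SUVR and corrected volumes throughout the
#' package.
#'
#' @param values 3D numeric array (all values finite).
#' @param spacing numeric length-3, voxel size in mm along each axis (> 0).
#' @param origin numeric length-3, physical coordinate of voxel (1,1,1).
#' @return An object of class `vol_image` with elements `values`, `spacing`,
#'   `origin`.
#' @export
vol_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) == 1L) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("vol_image: 'values' must be a 3D array")
  if (any(dim(values) < 1L)) stop("vol_image: all grid dimensions must be >= 1")
  if (!all(is.finite(values))) stop("vol_image: values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("vol_image: spacing must be 3 positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("vol_image: origin must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  cat(sprintf("<vol_image> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

is_vol_image <- function(x) inherits(x, "vol_image")

#' Gaussian point-spread-function model
#'
#' Spatially invariant isotropic Gaussian PSF parameterized by its
#' full-width-at-half-maximum in mm. The sampled kernel is truncated at
#' `truncation` standard deviations per axis and renormalized to sum to 1.
#'
#' @param fwhm_mm isotropic FWHM in mm (>= 0; 0 gives a delta kernel).
#' @param truncation kernel support radius in standard deviations (default 4).
#' @return Object of class `psf_model`.
#' @export
psf_model <- function(fwhm_mm, truncation = 4) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("psf_model: fwhm_mm must be a single value >= 0")
  if (truncation <= 0) stop("psf_model: truncation must be > 0")
  structure(list(fwhm_mm = as.numeric(fwhm_mm),
                 truncation = as.numeric(truncation)),
            class = "psf_model")
}

#' Sample a PSF kernel on a voxel grid
#'
#' Returns the normalized separable Gaussian kernel sampled at voxel centres,
#' truncated at `psf$truncation` SD along each axis (support is capped at the
#' grid extent so reflective padding stays well defined).
#'
#' @param psf a [psf_model()].
#' @param spacing per-axis voxel spacing in mm.
#' @param max_dim optional per-axis grid dimensions used to cap the support.
#' @return 3D array with odd dimensions summing to 1.
#' @export
psf_kernel <- function(psf, spacing, max_dim = NULL) {
  stopifnot(inherits(psf, "psf_model"))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sigma_mm <- psf$fwhm_mm / (2 * sqrt(2 * log(2)))
  ax <- vector("list", 3L)
  for (a in 1:3) {
    sig <- sigma_mm / spacing[a]
    r <- if (sig == 0) 0L else as.integer(ceiling(psf$truncation * sig))
    if (!is.null(max_dim)) r <- min(r, max(max_dim[a] - 1L, 0L))
    off <- seq(-r, r)
    ax[[a]] <- if (sig == 0) 1 else exp(-0.5 * (off / sig)^2)
  }
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(k) <- c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]]))
  k / sum(k)
}

# reflect ("symmetric") padding index map for one axis
reflect_index <- function(d, r) {
  if (r == 0L) return(seq_len(d))
  if (r > d) stop("reflective padding radius exceeds grid extent")
  c(rev(seq_len(r)), seq_len(d), d - seq_len(r) + 1L)
}

# place a centred kernel on a padded circular grid so its centre sits at (1,1,1)
kernel_on_grid <- function(kern, pd) {
  kd <- dim(kern)
  r <- (kd - 1L) %/% 2L
  kp <- array(0, pd)
  ix <- lapply(1:3, function(a) ((seq_len(kd[a]) - 1L - r[a]) %% pd[a]) + 1L)
  kp[ix[[1]], ix[[2]], ix[[3]]] <- kern
  kp
}

circ_conv3 <- function(a, kp) {
  Re(stats::fft(stats::fft(a) * stats::fft(kp), inverse = TRUE)) / length(a)
}

# precomputed plan for repeated reflect-padded convolutions on one grid
conv_plan <- function(d, kern) {
  kd <- dim(kern); r <- (kd - 1L) %/% 2L
  if (all(r == 0L)) {
    s <- sum(kern)
    return(function(arr) arr * s)
  }
  ix <- lapply(1:3, function(a) reflect_index(d[a], r[a]))
  pd <- d + 2L * r
  Kf <- stats::fft(kernel_on_grid(kern, pd))
  np <- prod(pd)
  function(arr) {
    ap <- arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    out <- Re(stats::fft(stats::fft(ap) * Kf, inverse = TRUE)) / np
    out[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3]),
        drop = FALSE]
  }
}

# linear convolution with reflective (symmetric) boundary padding
conv3_reflect <- function(arr, kern) {
  conv_plan(dim(arr), kern)(arr)
}

# fold one padded axis back onto the source grid (transpose of reflect_index)
fold_axis <- function(a, ix, d, axis) {
  dm <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dm[axis])
  fm <- rowsum(m, group = ix, reorder = TRUE)
  out <- array(fm, c(d, dm[perm[2]], dm[perm[3]]))
  aperm(out, order(perm))
}

# exact adjoint of conv3_reflect (symmetric kernels assumed symmetric-flipped)
conv3_reflect_adjoint <- function(arr, kern) {
  d <- dim(arr); kd <- dim(kern); r <- (kd - 1L) %/% 2L
  if (all(r == 0L)) return(arr * sum(kern))
  pd <- d + 2L * r
  bp <- array(0, pd)
  bp[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])] <- arr
  kflip <- kern[rev(seq_len(kd[1])), rev(seq_len(kd[2])), rev(seq_len(kd[3])),
                drop = FALSE]
  out <- circ_conv3(bp, kernel_on_grid(kflip, pd))
  for (a in 1:3) out <- fold_axis(out, reflect_index(d[a], r[a]), d[a], a)
  out
}

#' Convolve a volume with a PSF
#'
#' Linear shift-invariant blur with the sampled, renormalized Gaussian
#' kernel, computed in the frequency domain with reflective boundary
#' padding. A zero-FWHM PSF is the identity.
#'
#' @param image a [vol_image()].
#' @param psf a [psf_model()].
#' @return The blurred [vol_image()].
#' @export
convolve_psf <- function(image, psf) {
  stopifnot(is_vol_image(image))
  kern <- psf_kernel(psf, image$spacing, max_dim = dim(image$values))
  out <- conv3_reflect(image$values, kern)
  vol_image(out, image$spacing, image$origin)
}

#' Read a 3D NIfTI volume
#'
#' @param path a NIfTI-1 file (.nii or .nii.gz); must be 3D. For 4D dynamic
#'   PET, sum the temporal frames into a single static volume first.
#' @return A [vol_image()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] > 1L)
    stop("read_volume: input is 4D; sum the temporal frames into a 3D volume ",
         "before analysis (e.g. apply(x, 1:3, sum))")
  vals <- array(as.numeric(img), d[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  vol_image(vals, sp, org)
}

#' Write a volume as NIfTI-1
#'
#' @param image a [vol_image()] (or, with `datatype = "int32"`, an integer
#'   label array wrapped in a `vol_image`).
#' @param path output path (.nii or .nii.gz).
#' @param datatype on-disk datatype, `"float"` (default) or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path, datatype = "float") {
  stopifnot(is_vol_image(image))
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# seed-scoped RNG evaluation: runs expr under a local seed without
# disturbing the caller's RNG stream; seed = NULL uses the ambient stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a bounded child seed from a parent seed and a stage tag
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103 + h) %% .Machine$integer.max)
}
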