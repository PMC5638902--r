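#' Region-by-subject intensity matrix
#'
#' @param values m x n numeric matrix (regions x subjects), no missing
#'   entries.
#' @param region_labels length-m region ids.
#' @param subject_ids length-n subject ids.
#' @param group group name.
#' @return Object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, region_labels = seq_len(nrow(values)),
                             subject_ids = colnames(values),
                             group = "group") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("intensity_matrix: missing entries not allowed")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("intensity_matrix: need at least one region and one subject")
  if (length(region_labels) != nrow(values))
    stop("intensity_matrix: region_labels length mismatch")
  if (is.null(subject_ids))
    subject_ids <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- as.character(region_labels)
  colnames(values) <- subject_ids
  structure(list(values = values, region_labels = region_labels,
                 subject_ids = subject_ids, group = group),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d regions x %d subjects (group %s)\n",
              nrow(x$values), ncol(x$values), x$group))
  invisible(x)
}

region_voxel_index <- function(parcellation) {
  lab <- parcellation$labels
  m <- nrow(parcellation$regions)
  idx <- which(lab > 0)
  split(idx, factor(lab[idx], levels = seq_len(m)))
}

#' Region-mean intensity matrix
#'
#' Entry (s, t) is the mean of subject t's image over region s's binary
#' mask. The region mean is the standard mask-weighted mean
#' `sum(w * p) / sum(w)`.
#'
#' @param images list of [vol_image()], one per subject, on the
#'   parcellation's grid.
#' @param parcellation a [build_parcellation()] result.
#' @param subject_ids,group passed to [intensity_matrix()].
#' @return An [intensity_matrix()] (regions x subjects).
#' @export
region_mean_matrix <- function(images, parcellation, subject_ids = NULL,
                               group = "group") {
  by_region <- region_voxel_index(parcellation)
  empty <- vapply(by_region, length, 1L) == 0L
  if (any(empty))
    stop("region_mean_matrix: empty region mask for label(s) ",
         paste(which(empty), collapse = ", "))
  vals <- vapply(images, function(im) {
    stopifnot(is_vol_image(im))
    if (!all(dim(im$values) == dim(parcellation$labels)))
      stop("region_mean_matrix: image grid does not match parcellation")
    vapply(by_region, function(ix) mean(im$values[ix]), numeric(1))
  }, numeric(length(by_region)))
  vals <- matrix(vals, nrow = length(by_region))
  intensity_matrix(vals, region_labels = parcellation$regions$label,
                   subject_ids = subject_ids, group = group)
}

#' SUVR normalization by a reference region
#'
#' Divides a tracer volume voxelwise by its mean over the reference-region
#' mask, so the output's reference-region mean is exactly 1. Invariant to
#' global rescaling of the input.
#'
#' @param image a [vol_image()].
#' @param reference_mask logical array (same grid) or, with `parcellation`,
#'   an integer region label.
#' @param parcellation optional [build_parcellation()] used to resolve an
#'   integer `reference_mask` label.
#' @return The SUVR [vol_image()].
#' @export
suvr_normalize <- function(image, reference_mask, parcellation = NULL) {
  stopifnot(is_vol_image(image))
  if (is.numeric(reference_mask) && length(reference_mask) == 1L) {
    if (is.null(parcellation))
      stop("suvr_normalize: parcellation needed to resolve a label reference")
    reference_mask <- parcellation$labels == as.integer(reference_mask)
  }
  if (!any(reference_mask)) stop("suvr_normalize: reference mask is empty")
  ref <- mean(image$values[reference_mask])
  if (ref <= 0) stop("suvr_normalize: reference-region mean must be > 0")
  vol_image(image$values / ref, image$spacing, image$origin)
}

#' 10% interquartile mean
#'
#' Robust regional summary: the mean over the central 90% of sorted values.
#' Two normalizations are provided. `"as_printed"` follows the published
#' form `(9/10)/n * sum(x_(floor(0.05 n + 1)) .. x_(ceiling(0.95 n)))`
#' exactly; note it is not mean-preserving on constant input (it scales by
#' `0.9 * kept / n`). `"mean_preserving"` divides the trimmed sum by the
#' number of retained values instead.
#'
#' @param values numeric vector (n >= 1).
#' @param mode `"as_printed"` (default) or `"mean_preserving"`.
#' @return Scalar interquartile mean.
#' @export
interquartile_mean <- function(values, mode = c("as_printed",
                                                "mean_preserving")) {
  mode <- match.arg(mode)
  if (length(values) < 1L) stop("interquartile_mean: empty vector")
  x <- sort(values)
  n <- length(x)
  lo <- floor(0.05 * n + 1)
  hi <- ceiling(0.95 * n)
  s <- sum(x[lo:hi])
  if (mode == "as_printed") (9 / 10) / n * s else s / (hi - lo + 1)
}

#' Region IQM matrix
#'
#' Per-subject, per-region interquartile mean of voxel values, the robust
#' regional summary used for SUVR group statistics.
#'
#' @inheritParams region_mean_matrix
#' @param mode passed to [interquartile_mean()].
#' @return An [intensity_matrix()].
#' @export
region_iqm_matrix <- function(images, parcellation, subject_ids = NULL,
                              group = "group", mode = "as_printed") {
  by_region <- region_voxel_index(parcellation)
  empty <- vapply(by_region, length, 1L) == 0L
  if (any(empty))
    stop("region_iqm_matrix: empty region mask for label(s) ",
         paste(which(empty), collapse = ", "))
  vals <- vapply(images, function(im) {
    vapply(by_region, function(ix) interquartile_mean(im$values[ix], mode),
           numeric(1))
  }, numeric(length(by_region)))
  vals <- matrix(vals, nrow = length(by_region))
  intensity_matrix(vals, region_labels = parcellation$regions$label,
                   subject_ids = subject_ids, group = group)
}

#' Group-level regional SUVR statistics
#'
#' Per-region across-subject mean, sample standard deviation (n - 1
#' denominator) and coefficient of variation (SD/mean), emitted as a tidy
#' table keyed by (region, group, method) — one row per region.
#'
#' @param suvr_matrix an [intensity_matrix()] of per-subject regional values
#'   (n >= 2 subjects).
#' @param method method tag, e.g. `"uncorrected"`, `"JEPVC"`, `"LSPVC"`,
#'   `"GTM"`.
#' @return data.frame with columns `region`, `group`, `method`, `mean`,
#'   `sd`, `cov_s`.
#' @export
group_region_stats <- function(suvr_matrix, method = "uncorrected") {
  stopifnot(inherits(suvr_matrix, "intensity_matrix"))
  X <- suvr_matrix$values
  if (ncol(X) < 2L)
    stop("group_region_stats: need at least 2 subjects per group")
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  data.frame(region = suvr_matrix$region_labels,
             group = suvr_matrix$group,
             method = method,
             mean = mu,
             sd = sdv,
             cov_s = ifelse(mu > 0, sdv / mu, NA_real_),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an intensity matrix as TSV
#'
#' Region rows by subject columns with a `region` id column and a header row
#' of subject ids.
#'
#' @param x an [intensity_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(region = x$region_labels,
                   formatC(x$values, format = "g", digits = 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region", x$subject_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity matrix from TSV
#'
#' @param path TSV written by [write_intensity_tsv()].
#' @param group group name to attach.
#' @return An [intensity_matrix()].
#' @export
read_intensity_tsv <- function(path, group = "group") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  intensity_matrix(vals, region_labels = df[[1]],
                   subject_ids = colnames(df)[-1], group = group)
}
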