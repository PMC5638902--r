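#' Connectivity matrix with a pipeline-stage tag
#'
#' Group-level brain networks pass through a fixed sequence of stages:
#' `pearson` (correlation of region rows across subjects) -> `clipped`
#' (negatives zeroed) -> `zscored` (column standardization) ->
#' `normalized` (global-max scaling) -> `thresholded`. The stage tag makes
#' misordering detectable.
#'
#' @param weights m x m numeric matrix.
#' @param stage one of `"pearson"`, `"clipped"`, `"zscored"`,
#'   `"normalized"`, `"thresholded"`.
#' @param node_labels length-m node names.
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, stage, node_labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectivity_matrix: weights must be square")
  stage <- match.arg(stage, c("pearson", "clipped", "zscored", "normalized",
                              "thresholded"))
  if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(weights)))
  structure(list(weights = weights, stage = stage,
                 node_labels = node_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes, stage '%s'\n",
              nrow(x$weights), x$stage))
  invisible(x)
}

#' Group correlation network (clipped stage)
#'
#' Pearson correlation of region rows across subjects, with negative values
#' replaced by zero and unit diagonal.
#'
#' @param intensity an [intensity_matrix()] with at least 3 subjects.
#' @return A [connectivity_matrix()] at the `clipped` stage.
#' @export
correlation_network <- function(intensity) {
  stopifnot(inherits(intensity, "intensity_matrix"))
  X <- intensity$values
  if (ncol(X) < 3L)
    stop("correlation_network: need at least 3 subjects")
  v <- apply(X, 1, stats::var)
  if (any(v == 0))
    stop("correlation_network: zero-variance region(s): ",
         paste(intensity$region_labels[v == 0], collapse = ", "))
  C <- stats::cor(t(X))
  C[C < 0] <- 0
  diag(C) <- 1
  connectivity_matrix(C, "clipped",
                      node_labels = as.character(intensity$region_labels))
}

#' Column z-score standardization (zscored stage)
#'
#' Standardizes each column of the connectivity matrix to mean 0 and sample
#' standard deviation 1, reducing inter-subject scale differences between
#' group networks.
#'
#' @param weights a [connectivity_matrix()].
#' @return A [connectivity_matrix()] at the `zscored` stage.
#' @export
standardize_columns <- function(weights) {
  stopifnot(inherits(weights, "connectivity_matrix"))
  W <- weights$weights
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0))
    stop("standardize_columns: constant column(s): ",
         paste(weights$node_labels[sds == 0], collapse = ", "))
  Z <- scale(W, center = TRUE, scale = TRUE)
  attributes(Z)[c("scaled:center", "scaled:scale")] <- NULL
  connectivity_matrix(Z, "zscored", weights$node_labels)
}

#' Global-max normalization and proportional threshold (thresholded stage)
#'
#' Divides the weights by the global maximum (optionally a shared maximum
#' across a collection of group networks), re-symmetrizes by averaging with
#' the transpose (column z-scoring breaks symmetry), zeroes the diagonal,
#' and keeps the `floor(p * m * (m - 1) / 2)` largest off-diagonal weights
#' (stable tie-break by index order), zeroing the rest.
#'
#' @param weights a [connectivity_matrix()].
#' @param p proportion of connections to keep, in `[0, 1]`.
#' @param global_max optional shared maximum for inter-group comparability
#'   (defaults to this matrix's maximum).
#' @return A [connectivity_matrix()] at the `thresholded` stage.
#' @export
normalize_and_threshold <- function(weights, p = 0.1, global_max = NULL) {
  stopifnot(inherits(weights, "connectivity_matrix"))
  if (p < 0 || p > 1) stop("normalize_and_threshold: p must be in [0, 1]")
  W <- weights$weights
  if (is.null(global_max)) global_max <- max(W)
  if (global_max <= 0)
    stop("normalize_and_threshold: maximum connection value must be > 0")
  W <- W / global_max
  W <- (W + t(W)) / 2
  diag(W) <- 0
  m <- nrow(W)
  keep <- floor(p * m * (m - 1) / 2)
  up <- which(upper.tri(W))
  ord <- up[order(W[up], decreasing = TRUE)]   # stable: ties by index order
  Wt <- matrix(0, m, m)
  if (keep > 0) {
    sel <- ord[seq_len(min(keep, length(ord)))]
    Wt[sel] <- W[sel]
    Wt <- Wt + t(Wt)
  }
  connectivity_matrix(Wt, "thresholded", weights$node_labels)
}

#' Fixed-cutoff threshold (thresholded stage)
#'
#' Keeps off-diagonal weights at or above an absolute cutoff applied
#' uniformly (after global-max normalization and re-symmetrization). Applied
#' with a cutoff shared across groups this preserves between-group density
#' differences, which a per-network proportional threshold erases.
#'
#' @param weights a [connectivity_matrix()].
#' @param cutoff absolute weight cutoff (> 0).
#' @param global_max optional shared maximum (defaults to this matrix's).
#' @return A [connectivity_matrix()] at the `thresholded` stage.
#' @export
threshold_at <- function(weights, cutoff, global_max = NULL) {
  stopifnot(inherits(weights, "connectivity_matrix"))
  if (cutoff <= 0) stop("threshold_at: cutoff must be > 0")
  W <- weights$weights
  if (is.null(global_max)) global_max <- max(W)
  if (global_max <= 0) stop("threshold_at: maximum connection value must be > 0")
  W <- W / global_max
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < cutoff] <- 0
  connectivity_matrix(W, "thresholded", weights$node_labels)
}

#' Pooled proportional cutoff for a collection of networks
#'
#' Computes the single weight value such that a fraction `p` of all pooled
#' off-diagonal weights (after normalization by the collection-wide maximum
#' and re-symmetrization) lie at or above it. Applying [threshold_at()] with
#' this cutoff to every group network yields per-group densities that vary
#' around `p`.
#'
#' @param networks list of [connectivity_matrix()] at the `zscored` (or
#'   earlier) stage.
#' @param p pooled proportion to retain.
#' @return List with `cutoff` and `global_max`.
#' @export
pooled_cutoff <- function(networks, p = 0.1) {
  stopifnot(length(networks) >= 1)
  gm <- max(vapply(networks, function(w) max(w$weights), numeric(1)))
  if (gm <= 0) stop("pooled_cutoff: maximum connection value must be > 0")
  pool <- unlist(lapply(networks, function(w) {
    W <- w$weights / gm
    W <- (W + t(W)) / 2
    W[upper.tri(W)]
  }))
  k <- max(1L, floor(p * length(pool)))
  cutoff <- sort(pool, decreasing = TRUE)[k]
  list(cutoff = cutoff, global_max = gm)
}

#' Run the full network-construction pipeline for one group
#'
#' Pearson correlation -> clip negatives -> column z-score -> global-max
#' normalization -> threshold; stages applied in the fixed published order.
#'
#' @param intensity an [intensity_matrix()].
#' @param p proportion for the proportional threshold.
#' @param cutoff optional fixed cutoff; when given, [threshold_at()] replaces
#'   the proportional threshold.
#' @param global_max optional shared maximum across groups.
#' @return A [connectivity_matrix()] at the `thresholded` stage.
#' @export
build_network <- function(intensity, p = 0.1, cutoff = NULL,
                          global_max = NULL) {
  z <- standardize_columns(correlation_network(intensity))
  if (is.null(cutoff)) normalize_and_threshold(z, p, global_max)
  else threshold_at(z, cutoff, global_max)
}
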