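#' Feature set for the classification study
#'
#' @param matrix subjects x features numeric matrix (no missing values).
#' @param labels per-subject class labels (coerced to factor, 2 classes for
#'   the paired CV study).
#' @param provenance `"uncorrected"` or `"corrected"`.
#' @param descriptor `"hog"`, `"region_means"` or `"graph_signal"`.
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(matrix, labels,
                        provenance = c("uncorrected", "corrected"),
                        descriptor = c("region_means", "hog",
                                       "graph_signal")) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("feature_set: missing values not allowed")
  labels <- factor(labels)
  if (length(labels) != nrow(matrix))
    stop("feature_set: labels must align with matrix rows")
  structure(list(matrix = matrix, labels = labels,
                 provenance = match.arg(provenance),
                 descriptor = match.arg(descriptor)),
            class = "feature_set")
}

# replicate-padded central-difference gradients of a 2D slice
slice_gradients <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  sp <- s[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  gx <- (sp[3:(nr + 2), 2:(nc + 1)] - sp[1:nr, 2:(nc + 1)]) / 2
  gy <- (sp[2:(nr + 1), 3:(nc + 2)] - sp[2:(nr + 1), 1:nc]) / 2
  list(gx = gx, gy = gy)
}

hog_slice <- function(s, cell = 8, orientations = 9, block = 2) {
  g <- slice_gradients(s)
  mag <- sqrt(g$gx^2 + g$gy^2)
  theta <- atan2(g$gy, g$gx) %% pi            # unsigned orientations
  bin <- pmin(floor(theta / (pi / orientations)) + 1, orientations)
  nr <- nrow(s); nc <- ncol(s)
  ncx <- nr %/% cell; ncy <- nc %/% cell
  if (ncx < 1 || ncy < 1)
    stop("hog_features: cell size exceeds the slice extent")
  hist3 <- array(0, c(ncx, ncy, orientations))
  cx <- pmin((seq_len(nr) - 1L) %/% cell + 1L, ncx)
  cy <- pmin((seq_len(nc) - 1L) %/% cell + 1L, ncy)
  for (o in seq_len(orientations)) {
    mo <- mag * (bin == o)
    hist3[, , o] <- rowsum(t(rowsum(mo, cx)), cy)[seq_len(ncy), ,
                                                  drop = FALSE] |> t()
  }
  # L2 block normalization over block x block cell groups (zero-guard:
  # an all-zero block stays zero, so uniform slices give zero descriptors)
  nbx <- ncx - block + 1L; nby <- ncy - block + 1L
  if (nbx < 1 || nby < 1) { nbx <- 1L; nby <- 1L; block <- min(ncx, ncy) }
  out <- numeric(0)
  for (bx in seq_len(nbx)) for (by in seq_len(nby)) {
    v <- as.numeric(hist3[bx:(bx + block - 1L), by:(by + block - 1L), ])
    nrm <- sqrt(sum(v^2))
    out <- c(out, if (nrm > 0) v / nrm else v)
  }
  out
}

#' Histogram-of-oriented-gradients features of a volume
#'
#' 2D HOG (magnitude-weighted cell histograms of unsigned gradient
#' orientations, L2 block-normalized with a zero guard) computed on a set
#' of axial slices and concatenated. The descriptor length is fixed by the
#' configuration, independent of intensities.
#'
#' @param volume a [vol_image()].
#' @param slices axial (third-axis) slice indices; default 9 evenly spaced
#'   interior slices.
#' @param cell cell size in voxels (default 8).
#' @param orientations number of orientation bins over `[0, pi)` (default 9).
#' @param block block size in cells for normalization (default 2).
#' @return Numeric feature vector.
#' @export
hog_features <- function(volume, slices = NULL, cell = 8, orientations = 9,
                         block = 2) {
  stopifnot(is_vol_image(volume))
  nz <- dim(volume$values)[3]
  if (is.null(slices))
    slices <- unique(round(seq(1, nz, length.out = min(9, nz) + 2)[
      2:(min(9, nz) + 1)]))
  if (any(slices < 1 | slices > nz))
    stop("hog_features: slice index out of range (1..", nz, ")")
  unlist(lapply(slices, function(z)
    hog_slice(volume$values[, , z], cell, orientations, block)))
}

#' Graph-Laplacian subspace
#'
#' Builds the subspace spanned by the first `k` eigenvectors (ascending
#' eigenvalue — the low-frequency end) of the Laplacian `L = D - W` of a
#' thresholded group network.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @param k subspace dimension (>= 1).
#' @return Object of class `graph_subspace`: `laplacian`, `basis` (m x k,
#'   orthonormal), `eigenvalues` (ascending), `k`.
#' @export
graph_subspace <- function(weights, k) {
  W <- as_weight_matrix(weights)
  m <- nrow(W)
  if (k < 1 || k > m) stop("graph_subspace: k must be in 1..", m)
  L <- diag(rowSums(W)) - W
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_len(m))       # eigen() returns descending eigenvalues
  structure(list(laplacian = L,
                 basis = e$vectors[, ord[seq_len(k)], drop = FALSE],
                 eigenvalues = e$values[ord], k = as.integer(k)),
            class = "graph_subspace")
}

#' Matched-subspace-detection statistic
#'
#' Fraction of a graph signal's energy captured by a Laplacian subspace:
#' `||U_k U_k' x||^2 / ||x||^2`, in `[0, 1]`.
#'
#' @param signal numeric vector over the m nodes (non-zero).
#' @param subspace a [graph_subspace()].
#' @return Scalar in `[0, 1]`.
#' @export
msd_statistic <- function(signal, subspace) {
  stopifnot(inherits(subspace, "graph_subspace"))
  x <- as.numeric(signal)
  if (length(x) != nrow(subspace$basis))
    stop("msd_statistic: signal length does not match the subspace")
  nx <- sum(x^2)
  if (nx == 0) stop("msd_statistic: zero signal")
  px <- crossprod(subspace$basis, x)
  sum(px^2) / nx
}

# choose the smallest k capturing `energy` of the training signals, capped
msd_pick_k <- function(basis_full, X, energy = 0.9, cap) {
  proj <- X %*% basis_full               # subjects x m, coordinates
  cum <- apply(proj^2, 1, cumsum)        # m x subjects cumulative energy
  tot <- rowSums(proj^2)                 # per-subject total energy
  frac <- sweep(cum, 2, pmax(tot, .Machine$double.eps), "/")
  k <- max(apply(frac, 2, function(f) which(f >= energy)[1]), na.rm = TRUE)
  min(max(k, 1L), cap)
}

# Two-class matched subspace detector. Each class contributes an affine
# model: its training mean plus the span of the first k Laplacian
# eigenvectors of its training network. A test signal is assigned to the
# class whose subspace captures more of the signal's energy around that
# class's mean — equivalently, the smaller orthogonal residual
# ||(I - U_k U_k') (x - mu_c)||^2.
msd_train <- function(X, y, p = 0.1, energy = 0.9) {
  m <- ncol(X)
  cap <- max(1L, m %/% 4L)
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    im <- intensity_matrix(t(Xi), group = cl)
    net <- build_network(im, p = p)
    full <- graph_subspace(net, m)
    Xc <- sweep(Xi, 2, mu)
    k <- msd_pick_k(full$basis, Xc, energy, cap)
    list(mean = mu, subspace = graph_subspace(net, k))
  })
  names(models) <- classes
  list(models = models, classes = classes)
}

msd_predict <- function(model, X) {
  resid <- vapply(model$classes, function(cl) {
    mo <- model$models[[cl]]
    U <- mo$subspace$basis
    Xc <- sweep(X, 2, mo$mean)
    rowSums(Xc^2) - rowSums((Xc %*% U)^2)
  }, numeric(nrow(X)))
  resid <- matrix(resid, nrow = nrow(X))
  score <- resid[, 1] - resid[, 2]       # >0 favours the second class
  pred <- factor(model$classes[1 + (score > 0)], levels = model$classes)
  list(prediction = pred, score = score)
}

drop_constant_columns <- function(Xtr, Xte) {
  v <- apply(Xtr, 2, stats::var)
  keep <- which(v > 1e-12)
  if (!length(keep)) stop("classification: all features constant in training")
  list(train = Xtr[, keep, drop = FALSE], test = Xte[, keep, drop = FALSE])
}

fit_predict <- function(classifier, Xtr, ytr, Xte) {
  if (classifier == "svm") {
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dvm <- attr(pr, "decision.values")
    dv <- as.numeric(dvm)
    # e1071 names the column "A/B" with positive values favouring A;
    # orient the score so positive favours the second factor level
    cn <- colnames(dvm)[1]
    if (!is.null(cn) && sub("/.*$", "", cn) == levels(ytr)[1]) dv <- -dv
    list(prediction = pr, score = dv)
  } else if (classifier == "lda") {
    # high-dimensional descriptors (e.g. HOG) are reduced by a PCA learned
    # on the training fold only, keeping LDA's pooled covariance estimable
    if (ncol(Xtr) > nrow(Xtr) / 2) {
      k <- min(40L, nrow(Xtr) - 2L)
      pc <- stats::prcomp(Xtr, center = TRUE, rank. = k)
      Xtr <- stats::predict(pc, Xtr)
      Xte <- stats::predict(pc, Xte)
    }
    dc <- drop_constant_columns(Xtr, Xte)
    fit <- suppressWarnings(MASS::lda(dc$train, grouping = ytr))
    pr <- stats::predict(fit, dc$test)
    list(prediction = pr$class, score = pr$posterior[, 2])
  } else if (classifier == "msd") {
    model <- msd_train(Xtr, ytr)
    msd_predict(model, Xte)
  } else stop("unknown classifier: ", classifier)
}

stratified_folds <- function(y, k, max_redraws = 100) {
  n <- length(y)
  for (draw in seq_len(max_redraws)) {
    fold <- integer(n)
    for (cl in levels(y)) {
      ix <- which(y == cl)
      fold[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == nlevels(y), logical(1)))
    if (ok) return(fold)
  }
  stop("stratified_folds: could not draw folds with both classes in every ",
       "training split")
}

#' Paired repeated k-fold cross-validation
#'
#' Runs the corrected-versus-uncorrected classification study: for every
#' repetition one stratified fold assignment is drawn and applied
#' identically to the pre-PVC and post-PVC feature sets, the classifier is
#' fit with identical hyperparameters on both arms, and pooled test error
#' rates are recorded. Decision scores are pooled across repetitions for
#' the ROC curves.
#'
#' @param features_pre,features_post [feature_set()]s sharing subjects and
#'   labels (two classes).
#' @param classifier `"svm"`, `"lda"` or `"msd"`.
#' @param folds number of folds (default 10).
#' @param repetitions number of repetitions (default 200).
#' @param seed integer seed.
#' @return Object of class `cv_report`: `errors` (data.frame with columns
#'   `rep`, `error_pre`, `error_post`, `diff = error_pre - error_post`),
#'   `roc_pre`, `roc_post` (see [roc_curve()]), `classifier`, `folds`,
#'   `repetitions`, `seed`.
#' @export
repeated_kfold <- function(features_pre, features_post,
                           classifier = c("svm", "lda", "msd"),
                           folds = 10, repetitions = 200, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features_pre, "feature_set"),
            inherits(features_post, "feature_set"))
  if (!identical(features_pre$labels, features_post$labels))
    stop("repeated_kfold: pre and post feature sets must share labels")
  y <- features_pre$labels
  if (nlevels(y) != 2) stop("repeated_kfold: exactly two classes required")
  n <- length(y)
  arms <- list(pre = features_pre$matrix, post = features_post$matrix)
  res <- with_seed(seed, {
    err <- matrix(NA_real_, repetitions, 2,
                  dimnames = list(NULL, names(arms)))
    scores <- list(pre = numeric(0), post = numeric(0))
    score_labels <- list(pre = factor(), post = factor())
    for (r in seq_len(repetitions)) {
      fold <- stratified_folds(y, folds)
      for (arm in names(arms)) {
        X <- arms[[arm]]
        pred <- factor(rep(levels(y)[1], n), levels = levels(y))
        sc <- numeric(n)
        for (f in seq_len(folds)) {
          te <- fold == f
          fp <- fit_predict(classifier, X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE])
          pred[te] <- fp$prediction
          sc[te] <- fp$score
        }
        err[r, arm] <- mean(pred != y)
        scores[[arm]] <- c(scores[[arm]], sc)
        score_labels[[arm]] <- factor(c(as.character(score_labels[[arm]]),
                                        as.character(y)),
                                      levels = levels(y))
      }
    }
    list(err = err, scores = scores, score_labels = score_labels)
  })
  errors <- data.frame(rep = seq_len(repetitions),
                       error_pre = res$err[, "pre"],
                       error_post = res$err[, "post"])
  errors$diff <- errors$error_pre - errors$error_post
  structure(list(errors = errors,
                 roc_pre = roc_curve(res$scores$pre,
                                     res$score_labels$pre),
                 roc_post = roc_curve(res$scores$post,
                                      res$score_labels$post),
                 classifier = classifier, folds = folds,
                 repetitions = repetitions, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %s, %d-fold x %d reps\n",
                     "  mean error pre %.4f, post %.4f, ",
                     "median diff %+.4f\n  AUC pre %.4f, post %.4f\n"),
              x$classifier, x$folds, x$repetitions,
              mean(x$errors$error_pre), mean(x$errors$error_post),
              stats::median(x$errors$diff), x$roc_pre$auc, x$roc_post$auc))
  invisible(x)
}

#' ROC curve and area
#'
#' Builds the monotone step curve of detection rate (true-positive rate)
#' against false-alarm probability (false-positive rate) by sweeping a
#' threshold over the decision scores, and returns the trapezoidal area
#' (ties contribute diagonal segments, matching the concordant-pair
#' probability).
#'
#' @param scores numeric decision values (larger favours the positive
#'   class).
#' @param labels two-class labels; the second factor level is the positive
#'   class.
#' @return List with `points` (data.frame `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("roc_curve: both classes must be present")
  pos <- labels == levels(labels)[2]
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so ties produce diagonal segments
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(p, grp, sum)))
  fp <- c(0, cumsum(tapply(!p, grp, sum)))
  tpr <- tp / np
  fpr <- fp / nn
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
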