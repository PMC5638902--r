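#' Deconvolution settings
#'
#' Bundle of tunables shared by the joint-entropy and Van Cittert
#' deconvolution routines.
#'
#' @param je_weight multiplier on the joint-entropy penalty (default 3e3;
#'   see the methods vignette for the calibration on the bundled phantom).
#' @param max_iters iteration cap (default 50).
#' @param armijo named vector: `step` (initial step length), `backtrack`
#'   (backtracking factor in (0,1)), `c1` (sufficient-decrease constant).
#' @param vc_alpha Van Cittert step length (default 1.5).
#' @param vc_tol Van Cittert relative-update termination threshold
#'   (default 0.01).
#' @param nonneg enforce non-negativity of iterates (default TRUE).
#' @param je_bins number of Parzen intensity bins per axis (default 64).
#' @param je_bandwidth_scale Parzen kernel bandwidth in units of bin width
#'   (default 1).
#' @return Object of class `deconv_settings`.
#' @export
deconv_settings <- function(je_weight = 3e3, max_iters = 50,
                            armijo = c(step = 1, backtrack = 0.5, c1 = 1e-4),
                            vc_alpha = 1.5, vc_tol = 0.01, nonneg = TRUE,
                            je_bins = 64, je_bandwidth_scale = 1) {
  if (vc_alpha <= 0) stop("deconv_settings: vc_alpha must be > 0")
  if (vc_tol <= 0) stop("deconv_settings: vc_tol must be > 0")
  if (armijo[["backtrack"]] <= 0 || armijo[["backtrack"]] >= 1)
    stop("deconv_settings: armijo backtrack factor must be in (0,1)")
  if (je_weight < 0) stop("deconv_settings: je_weight must be >= 0")
  structure(list(je_weight = je_weight, max_iters = as.integer(max_iters),
                 armijo = armijo, vc_alpha = vc_alpha, vc_tol = vc_tol,
                 nonneg = isTRUE(nonneg), je_bins = as.integer(je_bins),
                 je_bandwidth_scale = je_bandwidth_scale),
            class = "deconv_settings")
}

# truncation (in SD) of the Parzen kernels
PARZEN_CUT <- 6

#' Parzen joint PDF of two images
#'
#' Gaussian-kernel (Parzen window) estimate of the joint density of paired
#' PET/MR voxel intensities on a regular bin grid. The discrete density is
#' renormalized so that `sum(p) * du * dv = 1` exactly.
#'
#' @param pet,mr [vol_image()]s on the same grid.
#' @param n_bins number of bins per intensity axis (>= 2).
#' @param bandwidths length-2 kernel SDs (PET, MR axes); default one bin
#'   width per axis.
#' @param pet_range,mr_range optional explicit intensity ranges for the bin
#'   grid (used by the optimizer to keep the grid fixed across iterates).
#' @return Object of class `joint_pdf`: `grid` (n_bins x n_bins density),
#'   `u`, `v` (bin centres), `bin_widths`, `bandwidths`, `norm` (raw mass
#'   before renormalization).
#' @export
estimate_joint_pdf <- function(pet, mr, n_bins = 64, bandwidths = NULL,
                               pet_range = NULL, mr_range = NULL) {
  stopifnot(is_vol_image(pet), is_vol_image(mr))
  if (!all(dim(pet$values) == dim(mr$values)))
    stop("estimate_joint_pdf: images must share a grid")
  if (n_bins < 2L) stop("estimate_joint_pdf: n_bins must be >= 2")
  x <- as.numeric(pet$values)
  y <- as.numeric(mr$values)
  if (is.null(pet_range)) pet_range <- range(x)
  if (is.null(mr_range)) mr_range <- range(y)
  if (diff(pet_range) <= 0 || diff(mr_range) <= 0)
    stop("estimate_joint_pdf: constant image (zero intensity range)")
  u <- seq(pet_range[1], pet_range[2], length.out = n_bins)
  v <- seq(mr_range[1], mr_range[2], length.out = n_bins)
  du <- u[2] - u[1]; dv <- v[2] - v[1]
  if (is.null(bandwidths)) bandwidths <- c(du, dv)
  q <- parzen_joint_raw(x, y, u, v, bandwidths[1], bandwidths[2], PARZEN_CUT)
  Z <- sum(q) * du * dv
  if (Z <= 0) stop("estimate_joint_pdf: no sample mass on the bin grid")
  structure(list(grid = q / Z, u = u, v = v, bin_widths = c(du, dv),
                 bandwidths = bandwidths, norm = Z),
            class = "joint_pdf")
}

#' Joint and marginal entropies of a joint PDF
#'
#' Returns the (differential, grid-discretized) joint entropy
#' `H = -sum(p log p) du dv` together with the marginal entropies; the
#' deconvolution penalty [je_penalty()] is exactly `H_joint`.
#'
#' @param jpdf a [estimate_joint_pdf()] result.
#' @return Named list `H_joint`, `H_u`, `H_v`.
#' @export
joint_entropy <- function(jpdf) {
  stopifnot(inherits(jpdf, "joint_pdf"))
  du <- jpdf$bin_widths[1]; dv <- jpdf$bin_widths[2]
  p <- jpdf$grid
  plogp <- ifelse(p > 0, p * log(p), 0)
  pu <- rowSums(p) * dv
  pv <- colSums(p) * du
  list(H_joint = -sum(plogp) * du * dv,
       H_u = -sum(ifelse(pu > 0, pu * log(pu), 0)) * du,
       H_v = -sum(ifelse(pv > 0, pv * log(pv), 0)) * dv)
}

#' Joint-entropy penalty value
#'
#' The anatomical-prior term added to the least-squares objective: the
#' joint entropy `JE = -sum_m sum_n du dv p(u_m, v_n) log p(u_m, v_n)`.
#' Minimizing LS + weight * JE concentrates the joint PET/MR intensity
#' distribution, favouring PET estimates whose intensity classes follow the
#' anatomy (a smooth image with boundaries sharp where the MR has them).
#'
#' @param jpdf a [estimate_joint_pdf()] result.
#' @return Scalar penalty value (the joint entropy).
#' @export
je_penalty <- function(jpdf) {
  du <- jpdf$bin_widths[1]; dv <- jpdf$bin_widths[2]
  p <- jpdf$grid
  -sum(ifelse(p > 0, p * log(p), 0)) * du * dv
}

# gradient of je_penalty with respect to the PET voxel values; includes the
# chain-rule term through the explicit renormalization of the discrete PDF
je_penalty_grad <- function(pet_values, mr_values, jpdf) {
  du <- jpdf$bin_widths[1]; dv <- jpdf$bin_widths[2]
  p <- jpdf$grid
  Z <- jpdf$norm
  logp <- matrix(0, nrow(p), ncol(p))
  pos <- p > 0
  logp[pos] <- log(p[pos])
  W1 <- -du * dv * (1 + logp)     # d(-p log p)/dp
  K <- sum(W1 * p) * Z            # = sum(W1 * q), q = p * Z
  C <- W1 / Z - (K / Z^2) * du * dv
  parzen_joint_grad(as.numeric(pet_values), as.numeric(mr_values),
                    jpdf$u, jpdf$v, jpdf$bandwidths[1], jpdf$bandwidths[2],
                    PARZEN_CUT, C)
}

#' Joint-entropy penalized deconvolution
#'
#' Partial volume correction by minimizing a least-squares data-fidelity
#' term plus a weighted joint-entropy penalty between the PET estimate and
#' a co-registered anatomical MR image. Minimization is projected gradient
#' descent under a non-negativity constraint, with backtracking (Armijo)
#' line search, so the objective trace is non-increasing by construction.
#' The Parzen bin grid is frozen from the observed image at the start
#' (extended by a margin) so the objective stays smooth across iterates.
#'
#' @param observed observed (blurred) PET [vol_image()].
#' @param mr anatomical [vol_image()] on the same grid.
#' @param psf a [psf_model()].
#' @param settings a [deconv_settings()].
#' @return List with `corrected` ([vol_image()]) and `trace` (numeric vector
#'   of objective values, one per accepted iterate, attribute `converged`).
#' @export
je_deconvolve <- function(observed, mr, psf,
                          settings = deconv_settings()) {
  stopifnot(is_vol_image(observed), is_vol_image(mr),
            inherits(settings, "deconv_settings"))
  if (!all(dim(observed$values) == dim(mr$values)))
    stop("je_deconvolve: observed and mr must share a grid")
  d <- dim(observed$values)
  kern <- psf_kernel(psf, observed$spacing, max_dim = d)
  conv <- conv_plan(d, kern)
  obs <- observed$values
  mrv <- mr$values
  w <- settings$je_weight

  # frozen intensity grid: observed range widened so deconvolved iterates
  # (which recover contrast beyond the blurred range) stay on the grid
  rng <- range(obs)
  margin <- 0.5 * diff(rng) + 1e-12
  pet_range <- c(max(0, rng[1] - margin), rng[2] + margin)
  mr_range <- range(mrv)
  use_je <- w > 0 && diff(mr_range) > 0

  jpdf_of <- function(t) {
    bw <- settings$je_bandwidth_scale *
      c(diff(pet_range) / (settings$je_bins - 1),
        max(diff(mr_range), 1) / (settings$je_bins - 1))
    estimate_joint_pdf(vol_image(pmax(t, 0), observed$spacing),
                       vol_image(mrv, observed$spacing),
                       n_bins = settings$je_bins, bandwidths = bw,
                       pet_range = pet_range, mr_range = mr_range)
  }
  objective <- function(t) {
    r <- obs - conv(t)
    f <- sum(r * r)
    if (use_je) f <- f + w * je_penalty(jpdf_of(t))
    f
  }
  gradient <- function(t) {
    g <- 2 * conv3_reflect_adjoint(conv(t) - obs, kern)
    if (use_je) {
      jp <- jpdf_of(t)
      g <- g + w * array(je_penalty_grad(t, mrv, jp), d)
    }
    g
  }

  t_cur <- obs
  f_cur <- objective(t_cur)
  trace <- f_cur
  converged <- FALSE
  c1 <- settings$armijo[["c1"]]
  beta <- settings$armijo[["backtrack"]]
  for (k in seq_len(settings$max_iters)) {
    g <- gradient(t_cur)
    s <- settings$armijo[["step"]]
    accepted <- FALSE
    for (ls in 1:40) {
      t_new <- t_cur - s * g
      if (settings$nonneg) t_new <- pmax(t_new, 0)
      dt <- t_new - t_cur
      dec <- sum(g * dt)
      f_new <- objective(t_new)
      if (f_new <= f_cur + c1 * dec) { accepted <- TRUE; break }
      s <- s * beta
    }
    if (!accepted || sqrt(sum((t_new - t_cur)^2)) <=
        1e-10 * (1 + sqrt(sum(t_cur^2)))) {
      converged <- TRUE
      break
    }
    t_cur <- t_new
    f_cur <- f_new
    trace <- c(trace, f_cur)
  }
  # if the iteration cap was hit before stationarity, the last accepted
  # (best) iterate is returned and the trace is flagged non-converged
  attr(trace, "converged") <- converged
  list(corrected = vol_image(t_cur, observed$spacing, observed$origin),
       trace = trace)
}

#' Modified Van Cittert deconvolution
#'
#' Iterative least-squares deblurring
#' `t_0 = i; t_{k+1} = t_k + alpha * (h * (i - h * t_k))`, terminated when
#' the relative update `||t_{k+1} - t_k|| / ||i||` falls below `vc_tol`
#' (default 0.01) or at `max_iters`. A divergence guard stops the iteration
#' if the least-squares objective increases for five consecutive steps.
#'
#' @param observed observed PET [vol_image()].
#' @param psf a [psf_model()].
#' @param settings a [deconv_settings()] (`vc_alpha`, `vc_tol`, `max_iters`,
#'   `nonneg` are used).
#' @return Corrected [vol_image()] with attributes `iterations`,
#'   `final_ratio` (the termination ratio at the stopping step) and
#'   `diverged`.
#' @export
vc_deconvolve <- function(observed, psf, settings = deconv_settings()) {
  stopifnot(is_vol_image(observed), inherits(settings, "deconv_settings"))
  d <- dim(observed$values)
  kern <- psf_kernel(psf, observed$spacing, max_dim = d)
  conv <- conv_plan(d, kern)
  obs <- observed$values
  denom <- sqrt(sum(obs^2))
  if (denom == 0) denom <- 1
  t_cur <- obs
  ls_prev <- Inf
  n_incr <- 0L
  diverged <- FALSE
  ratio <- NA_real_
  iters <- 0L
  for (k in seq_len(settings$max_iters)) {
    resid <- obs - conv(t_cur)
    t_new <- t_cur + settings$vc_alpha * conv(resid)
    if (settings$nonneg) t_new <- pmax(t_new, 0)
    ratio <- sqrt(sum((t_new - t_cur)^2)) / denom
    ls <- sum((obs - conv(t_new))^2)
    if (ls > ls_prev) n_incr <- n_incr + 1L else n_incr <- 0L
    t_cur <- t_new
    iters <- k
    if (n_incr >= 5L) { diverged <- TRUE; break }
    ls_prev <- ls
    if (ratio < settings$vc_tol) break
  }
  if (diverged)
    warning("vc_deconvolve: least-squares objective increased for 5 ",
            "consecutive iterations; stopping early")
  out <- vol_image(t_cur, observed$spacing, observed$origin)
  attr(out, "iterations") <- iters
  attr(out, "final_ratio") <- ratio
  attr(out, "diverged") <- diverged
  out
}

#' Regional spread functions
#'
#' RSF_i is region i's binary indicator convolved with the PSF. With the
#' background region included, the RSFs form a partition of unity (they sum
#' to 1 at every voxel) because the indicators tile the grid and the kernel
#' sums to 1.
#'
#' @param parcellation a [build_parcellation()] result.
#' @param psf a [psf_model()].
#' @param include_background append the background (label 0) RSF as the last
#'   element (default FALSE).
#' @return Named list of 3D arrays, one per region.
#' @export
region_spread_functions <- function(parcellation, psf,
                                    include_background = FALSE) {
  lab <- parcellation$labels
  d <- dim(lab)
  m <- nrow(parcellation$regions)
  counts <- tabulate(lab[lab > 0], nbins = m)
  if (any(counts == 0L))
    stop("region_spread_functions: empty region(s): ",
         paste(which(counts == 0L), collapse = ", "))
  kern <- psf_kernel(psf, parcellation$spacing, max_dim = d)
  conv <- conv_plan(d, kern)
  labs <- seq_len(m)
  if (include_background) labs <- c(labs, 0L)
  out <- lapply(labs, function(l) conv(array(as.numeric(lab == l), d)))
  names(out) <- ifelse(labs == 0L, "background",
                       parcellation$regions$name[labs])
  out
}

#' Geometric transfer matrix system
#'
#' Assembles the regional transfer matrix Omega with
#' `omega[j, i] = (1 / n_vox(j)) * sum_{r in ROI_j} RSF_i(r)` — row j gives
#' the contributions of every source region i to the observed mean of
#' region j.
#'
#' @param parcellation a [build_parcellation()] result.
#' @param psf a [psf_model()].
#' @param include_background append a background region as the last
#'   row/column so rows sum to 1 (default FALSE).
#' @return Object of class `gtm_system`: `omega` (m x m), `rsf_integrals`
#'   (raw per-pair RSF sums over target regions), `voxel_counts`,
#'   `region_labels`.
#' @export
gtm_matrix <- function(parcellation, psf, include_background = FALSE) {
  lab <- parcellation$labels
  d <- dim(lab)
  m <- nrow(parcellation$regions)
  counts <- tabulate(lab[lab > 0], nbins = m)
  if (any(counts == 0L))
    stop("gtm_matrix: empty region(s): ",
         paste(which(counts == 0L), collapse = ", "))
  kern <- psf_kernel(psf, parcellation$spacing, max_dim = d)
  conv <- conv_plan(d, kern)
  labs <- seq_len(m)
  if (include_background) {
    labs <- c(labs, 0L)
    counts <- c(counts, sum(lab == 0L))
  }
  nr <- length(labs)
  by_region <- lapply(labs, function(l) which(lab == l))
  integrals <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    rsf <- conv(array(as.numeric(lab == labs[i]), d))
    integrals[, i] <- vapply(by_region, function(ix) sum(rsf[ix]), numeric(1))
  }
  omega <- integrals / counts   # divides row j by n_vox(j), recycled by row
  kap <- kappa(omega, exact = FALSE)
  if (!is.finite(kap) || kap > 1e8)
    stop("gtm_matrix: transfer matrix is ill-conditioned (condition number ",
         format(kap, digits = 3), "); regions may be too small relative to ",
         "the PSF FWHM")
  structure(list(omega = omega, rsf_integrals = integrals,
                 voxel_counts = counts,
                 region_labels = labs),
            class = "gtm_system")
}

#' GTM correction of observed regional means
#'
#' Solves the linear system `t = Omega T` for the true regional means `T`
#' given observed means `t`.
#'
#' @param observed_means numeric vector of length m (or an m x n matrix of
#'   per-subject columns).
#' @param system a [gtm_matrix()] result.
#' @return Corrected means, same shape as the input.
#' @export
gtm_correct <- function(observed_means, system) {
  stopifnot(inherits(system, "gtm_system"))
  om <- system$omega
  tmat <- as.matrix(observed_means)
  if (nrow(tmat) != nrow(om))
    stop("gtm_correct: expected ", nrow(om), " regional means")
  Tm <- solve(om, tmat)
  res <- sqrt(colSums((om %*% Tm - tmat)^2)) /
    pmax(sqrt(colSums(tmat^2)), .Machine$double.eps)
  if (any(res > 1e-8))
    stop("gtm_correct: linear solve residual exceeds 1e-8; Omega may be ",
         "singular")
  if (is.matrix(observed_means)) Tm else drop(Tm)
}
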