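test_that("Parzen joint PDF is a normalized density with sane entropies", {
  pet <- rand_volume(c(8, 8, 8), seed = 3, lo = 0, hi = 10)
  mr <- rand_volume(c(8, 8, 8), seed = 4, lo = 0, hi = 100)
  jp <- estimate_joint_pdf(pet, mr, n_bins = 32)
  expect_lt(abs(sum(jp$grid) * prod(jp$bin_widths) - 1), 1e-6)
  expect_true(all(jp$grid >= 0))
  # independent images: joint entropy ~ sum of marginals (within 5%)
  H <- joint_entropy(jp)
  expect_lt(abs(H$H_joint - H$H_u - H$H_v) / abs(H$H_joint), 0.05)
  # identical images after rescale: joint entropy collapses towards the
  # marginal (mass concentrates on the diagonal)
  jp2 <- estimate_joint_pdf(pet, vol_image(pet$values * 10, pet$spacing),
                            n_bins = 32)
  H2 <- joint_entropy(jp2)
  expect_lt(H2$H_joint, H$H_joint)
  expect_lt(abs(H2$H_joint - (H2$H_u + log(10))) / abs(H2$H_joint), 0.15)
  expect_error(estimate_joint_pdf(pet, rand_volume(c(6, 6, 6))), "grid")
  expect_error(estimate_joint_pdf(pet, vol_image(array(1, c(8, 8, 8)))),
               "constant")
})

test_that("JE penalty gradient matches central finite differences", {
  d <- c(8, 8, 8)
  pet <- rand_volume(d, seed = 5, lo = 0, hi = 10)
  mr <- rand_volume(d, seed = 6, lo = 0, hi = 100)
  pr <- c(-2, 12); mrr <- range(mr$values)
  jp <- estimate_joint_pdf(pet, mr, 32, pet_range = pr, mr_range = mrr)
  g <- pvcnet:::je_penalty_grad(pet$values, mr$values, jp)
  f <- function(x) je_penalty(estimate_joint_pdf(
    vol_image(array(x, d)), mr, 32, pet_range = pr, mr_range = mrr))
  x0 <- as.numeric(pet$values)
  set.seed(7)
  idx <- sample(length(x0), 15)
  eps <- 1e-4
  fd <- vapply(idx, function(i) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(abs(fd), 1e-12)), 1e-4)
})

test_that("JE deconvolution is a fixed point for delta PSF and no penalty", {
  obs <- rand_volume(c(8, 8, 8), seed = 8)
  mr <- rand_volume(c(8, 8, 8), seed = 9, lo = 0, hi = 100)
  out <- je_deconvolve(obs, mr, psf_model(0),
                       deconv_settings(je_weight = 0, max_iters = 5))
  expect_equal(out$corrected$values, obs$values)
  expect_true(attr(out$trace, "converged"))
})

test_that("JE objective trace is monotone non-increasing (Armijo)", {
  parc <- build_parcellation(c(16, 16, 16), c(2, 2, 2), 3, seed = 2)
  rs <- render_subject(parc, c(2, 5, 8))
  psf <- psf_model(6)
  obs <- simulate_acquisition(rs$true_pet, psf, 0.3, seed = 4)
  out <- je_deconvolve(obs, rs$mr, psf, deconv_settings(max_iters = 8))
  expect_true(all(diff(out$trace) <= 1e-9))
  expect_true(all(out$corrected$values >= 0))
})

test_that("JE correction reduces region-mean RMSE on a blurred phantom", {
  parc <- build_parcellation(c(20, 20, 20), c(2, 2, 2), 2, seed = 5)
  acts <- c(2, 7)
  rs <- render_subject(parc, acts)
  psf <- psf_model(6)
  obs <- simulate_acquisition(rs$true_pet, psf, 0, seed = 1)
  out <- je_deconvolve(obs, rs$mr, psf, deconv_settings(max_iters = 10))
  rmse <- function(v)
    sqrt(mean((region_mean_matrix(list(v), parc)$values[, 1] - acts)^2))
  expect_lt(rmse(out$corrected), rmse(obs))
})

test_that("Van Cittert recovers edges and terminates on the update ratio", {
  # 1D two-box signal: edge contrast strictly increases after correction
  sig <- array(0, c(64, 1, 1))
  sig[10:30, 1, 1] <- 2
  sig[35:55, 1, 1] <- 6
  img <- vol_image(sig, c(2, 2, 2))
  psf <- psf_model(8)
  obs <- convolve_psf(img, psf)
  vc <- vc_deconvolve(obs, psf)
  contrast <- function(v) max(v$values[30:40]) - min(v$values[30:40])
  expect_gt(contrast(vc), contrast(obs))
  expect_lt(attr(vc, "final_ratio"), 0.01)
  expect_false(attr(vc, "diverged"))
  # delta PSF: the first update is zero and the input is returned
  same <- vc_deconvolve(img, psf_model(0))
  expect_equal(same$values, img$values)
  expect_equal(attr(same, "iterations"), 1L)
})

test_that("region spread functions are blurred indicators tiling space", {
  parc <- parc_1d(24)
  psf <- psf_model(6)
  rsf <- region_spread_functions(parc, psf, include_background = TRUE)
  expect_length(rsf, 3L)
  total <- Reduce(`+`, rsf)
  expect_lt(max(abs(total - 1)), 1e-3)
  # matches direct convolution of the indicator
  kern <- psf_kernel(psf, parc$spacing, max_dim = dim(parc$labels))
  ind <- array(as.numeric(parc$labels == 1L), dim(parc$labels))
  expect_lt(max(abs(rsf[[1]] - brute_conv3(ind, kern))), 1e-8)
  expect_true(all(rsf[[1]] >= -1e-12 & rsf[[1]] <= 1 + 1e-12))
  # delta PSF: RSF equals the binary mask
  rsf0 <- region_spread_functions(parc, psf_model(0))
  expect_equal(rsf0[[2]], array(as.numeric(parc$labels == 2L),
                                dim(parc$labels)))
  # empty region is named in the error
  bad <- parc
  bad$labels[bad$labels == 2L] <- 1L
  expect_error(region_spread_functions(bad, psf), "2")
})

test_that("GTM matrix follows the row convention and known symmetries", {
  parc <- parc_1d(24, split = 12)
  psf <- psf_model(6)
  gt <- gtm_matrix(parc, psf, include_background = TRUE)
  expect_lt(max(abs(rowSums(gt$omega) - 1)), 1e-3)
  # each omega[j, i] equals the RSF_i sum over ROI_j / n_vox(j)
  rsf <- region_spread_functions(parc, psf, include_background = TRUE)
  for (j in 1:2) for (i in 1:2) {
    direct <- sum(rsf[[i]][parc$labels == j]) / sum(parc$labels == j)
    expect_lt(abs(gt$omega[j, i] - direct), 1e-10)
  }
  # delta PSF: identity
  gt0 <- gtm_matrix(parc, psf_model(0))
  expect_equal(unname(gt0$omega), diag(2))
  # two equal half-volumes under a symmetric PSF: symmetric omega
  parc2 <- parc_1d(26, split = 13)
  parc2$labels[c(1, 26), 1, 1] <- c(1L, 2L)  # fill ends: equal halves
  gt2 <- gtm_matrix(parc2, psf)
  expect_lt(abs(gt2$omega[1, 2] - gt2$omega[2, 1]), 1e-10)
})

test_that("GTM correction solves the transfer system exactly", {
  om <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  sys <- structure(list(omega = om, rsf_integrals = om,
                        voxel_counts = c(1, 1), region_labels = 1:2),
                   class = "gtm_system")
  expect_equal(gtm_correct(c(0.68, 0.32), sys), c(0.8, 0.2))
  expect_equal(gtm_correct(c(1, 2), structure(list(
    omega = diag(2), rsf_integrals = diag(2), voxel_counts = c(1, 1),
    region_labels = 1:2), class = "gtm_system")), c(1, 2))
  # ground truth recovery on a noiseless blurred phantom
  parc <- build_parcellation(c(24, 24, 24), c(2, 2, 2), 5, seed = 9)
  acts <- c(1, 3, 5, 7, 9)
  rs <- render_subject(parc, acts)
  psf <- psf_model(6)
  obs <- simulate_acquisition(rs$true_pet, psf, 0)
  gt <- gtm_matrix(parc, psf)
  t_obs <- region_mean_matrix(list(obs), parc)$values[, 1]
  rec <- gtm_correct(t_obs, gt)
  expect_lt(max(abs(rec - acts) / acts), 1e-6)
})
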