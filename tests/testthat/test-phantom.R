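test_that("parcellation partitions the brain mask into the requested parcels", {
  parc <- build_parcellation(c(24, 24, 24), c(2, 2, 2), n_regions = 12,
                             seed = 3)
  brain <- parc$labels > 0
  expect_setequal(unique(as.integer(parc$labels[brain])), 1:12)
  expect_equal(nrow(parc$regions), 12L)
  # tissue classes live inside the brain mask
  expect_true(all(parc$tissue[!brain] == 0L))
  # degenerate single parcel
  p1 <- build_parcellation(c(16, 16, 16), c(2, 2, 2), n_regions = 1,
                           seed = 1)
  expect_true(all(p1$labels[p1$labels > 0] == 1L))
  expect_equal(nrow(p1$regions), 1L)
})

test_that("parcellation is deterministic under a fixed seed and validates", {
  a <- build_parcellation(c(20, 20, 20), c(2, 2, 2), 8, seed = 11)
  b <- build_parcellation(c(20, 20, 20), c(2, 2, 2), 8, seed = 11)
  expect_identical(a$labels, b$labels)
  expect_error(build_parcellation(c(6, 6, 6), c(2, 2, 2), 1e6, seed = 1),
               "exceeds")
  expect_error(build_parcellation(c(0, 8, 8), c(2, 2, 2), 4), "positive")
})

test_that("cohort activities reproduce the requested correlation structure", {
  # identity correlation: off-diagonal empirical correlations near 0
  spec <- cohort_spec(n_regions = 10, groups = c(NC = 10000),
                      within_r = c(NC = 0), uplift = c(NC = 0),
                      n_blocks = 3, wm_frac = 0, seed = 2)
  A <- sample_cohort_activities(spec)$NC$values
  C <- cor(t(A))
  expect_lt(max(abs(C[upper.tri(C)])), 0.03)
  # two-block structure at r = 0.8 recovered within 0.02
  spec2 <- cohort_spec(n_regions = 12, groups = c(NC = 10000),
                       within_r = c(NC = 0.8), uplift = c(NC = 0),
                       n_blocks = 2, wm_frac = 0, seed = 2)
  A2 <- sample_cohort_activities(spec2)$NC$values
  C2 <- cor(t(A2))
  blk <- attr(spec2$correlation_model$NC, "block")
  same <- outer(blk, blk, `==`) & upper.tri(C2)
  expect_lt(max(abs(C2[same] - 0.8)), 0.02)
  # group means within 2%
  expect_lt(max(abs(rowMeans(A2) / spec2$region_means[, "NC"] - 1)), 0.02)
})

test_that("cohort sampling is seed-deterministic and rejects bad inputs", {
  spec <- cohort_spec(n_regions = 6, groups = c(NC = 5), n_blocks = 2,
                      within_r = c(NC = 0.5), uplift = c(NC = 0),
                      wm_frac = 0, seed = 4)
  expect_identical(sample_cohort_activities(spec)$NC$values,
                   sample_cohort_activities(spec)$NC$values)
  bad <- spec
  bad$correlation_model$NC <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(sample_cohort_activities(bad), "NC")
  expect_error(cohort_spec(groups = c(NC = 1)), "counts")
})

test_that("rendered subjects are piecewise constant over parcels", {
  parc <- build_parcellation(c(12, 12, 12), c(2, 2, 2), 2, seed = 6)
  rs <- render_subject(parc, c(2, 5))
  for (r in 1:2) {
    vox <- rs$true_pet$values[parc$labels == r]
    expect_true(all(vox == c(2, 5)[r]))
  }
  expect_true(all(rs$true_pet$values[parc$labels == 0] == 0))
  # constant activities give a constant brain
  rs2 <- render_subject(parc, c(4, 4))
  expect_true(all(rs2$true_pet$values[parc$labels > 0] == 4))
  expect_error(render_subject(parc, 1:5), "activities")
  # the MR volume distinguishes tissue classes on the same grid
  expect_equal(dim(rs$mr$values), dim(rs$true_pet$values))
  expect_gt(length(unique(as.numeric(rs$mr$values))), 2)
})

test_that("acquisition conserves activity, reduces contrast, seeds noise", {
  parc <- build_parcellation(c(24, 24, 24), c(2, 2, 2), 2, seed = 8)
  rs <- render_subject(parc, c(2, 8))
  psf <- psf_model(6)
  obs <- simulate_acquisition(rs$true_pet, psf, noise_sd = 0)
  expect_lt(abs(sum(obs$values) / sum(rs$true_pet$values) - 1), 0.005)
  # blur strictly reduces between-region contrast
  m_true <- region_mean_matrix(list(rs$true_pet), parc)$values[, 1]
  m_obs <- region_mean_matrix(list(obs), parc)$values[, 1]
  expect_lt(abs(diff(m_obs)), abs(diff(m_true)))
  # delta PSF, zero noise: identity
  same <- simulate_acquisition(rs$true_pet, psf_model(0), 0)
  expect_equal(same$values, rs$true_pet$values)
  # seeded noise is reproducible, and negative noise is rejected
  n1 <- simulate_acquisition(rs$true_pet, psf, 0.5, seed = 3)
  n2 <- simulate_acquisition(rs$true_pet, psf, 0.5, seed = 3)
  expect_identical(n1$values, n2$values)
  expect_error(simulate_acquisition(rs$true_pet, psf, -1), "noise_sd")
})
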