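test_that("correlation networks match the Pearson definition and clip", {
  # 3 regions x 4 subjects toy, verified against the definitional formula
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                4, 3, 2, 1), 3, 4, byrow = TRUE)
  net <- correlation_network(intensity_matrix(X))
  pearson <- function(a, b) {
    ca <- a - mean(a); cb <- b - mean(b)
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expected <- max(pearson(X[i, ], X[j, ]), 0)
    if (i == j) expected <- 1
    expect_lt(abs(net$weights[i, j] - expected), 1e-12)
  }
  expect_identical(net$stage, "clipped")
  # identical rows correlate at 1; anti-correlated rows clip to 0
  X2 <- rbind(1:4, 1:4, 4:1)
  net2 <- correlation_network(intensity_matrix(X2 + 0.01 * matrix(rnorm(12), 3)))
  expect_gt(net2$weights[1, 2], 0.99)
  X3 <- rbind(1:4, 4:1, c(2, 4, 1, 3))
  net3 <- correlation_network(intensity_matrix(X3))
  expect_equal(net3$weights[1, 2], 0)
  expect_error(correlation_network(intensity_matrix(matrix(1, 2, 4))),
               "zero-variance")
  expect_error(correlation_network(intensity_matrix(matrix(1:4, 2, 2))),
               "3 subjects")
})

test_that("column standardization gives exact z-scores and idempotence", {
  W <- matrix(c(1, 2, 3, 2, 4, 9, 5, 1, 2), 3, 3)
  z <- standardize_columns(connectivity_matrix(W, "clipped"))
  expect_equal(z$weights[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z$weights))), 1e-12)
  expect_lt(max(abs(apply(z$weights, 2, sd) - 1)), 1e-12)
  z2 <- standardize_columns(z)
  expect_lt(max(abs(z2$weights - z$weights)), 1e-12)
  expect_identical(z$stage, "zscored")
  expect_error(standardize_columns(connectivity_matrix(matrix(1, 3, 3),
                                                       "clipped")),
               "constant")
})

test_that("proportional threshold keeps exactly the floor-count edges", {
  set.seed(4)
  m <- 90
  W <- matrix(0, m, m)
  up <- which(upper.tri(W))
  W[up] <- runif(length(up))          # dense, distinct
  W <- W + t(W)
  cm <- connectivity_matrix(W, "zscored")
  thr <- normalize_and_threshold(cm, p = 0.1)
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0),
               floor(0.1 * m * (m - 1) / 2))   # 400 edges
  expect_identical(thr$stage, "thresholded")
  expect_true(isSymmetric(thr$weights))
  expect_equal(max(thr$weights), 1)   # surviving maximum is 1 after scaling
  # bounds
  all_kept <- normalize_and_threshold(cm, p = 1)
  expect_equal(sum(all_kept$weights[upper.tri(W)] > 0), length(up))
  none <- normalize_and_threshold(cm, p = 0)
  expect_equal(sum(none$weights), 0)
  expect_error(normalize_and_threshold(
    connectivity_matrix(matrix(0, 3, 3), "zscored"), 0.1), "> 0")
})

test_that("fixed-cutoff thresholding preserves between-group differences", {
  set.seed(5)
  strong <- matrix(runif(64, 0.5, 1), 8, 8); strong <- (strong + t(strong)) / 2
  weak <- strong * 0.4
  nets <- list(connectivity_matrix(strong, "zscored"),
               connectivity_matrix(weak, "zscored"))
  pc <- pooled_cutoff(nets, p = 0.3)
  d1 <- degree_and_density(threshold_at(nets[[1]], pc$cutoff,
                                        pc$global_max))$density
  d2 <- degree_and_density(threshold_at(nets[[2]], pc$cutoff,
                                        pc$global_max))$density
  expect_gt(d1, d2)
})

test_that("degree, density and efficiency match hand-enumerated toys", {
  tri <- matrix(1, 3, 3) - diag(3)
  dd <- degree_and_density(tri)
  expect_equal(unname(dd$degree), c(2, 2, 2))
  expect_equal(dd$density, 1)
  expect_equal(global_efficiency(tri), 1)
  # N = 4, K = 3 -> d = 0.5
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  A <- A + t(A)
  expect_equal(degree_and_density(A)$density, 0.5)
  # 3-node path: pairs at distance 1, 1, 2 -> E = 5/6
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(global_efficiency(P3), 5 / 6)
  # two isolated nodes and the empty graph
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  e <- degree_and_density(matrix(0, 4, 4))
  expect_true(all(e$degree == 0) && e$density == 0)
})

test_that("clustering matches brute-force triangle enumeration", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(as.numeric(clustering_coefficient(tri, "binary")), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(as.numeric(clustering_coefficient(star)), 0)
  # weighted 4-node toy vs exhaustive geometric-mean triangle count
  set.seed(6)
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.4, 0, 0.7, 0.5, 0.8)
  W <- W + t(W)
  Wh <- W / max(W)
  n <- 4
  cc_manual <- sapply(seq_len(n), function(i) {
    k <- sum(W[i, ] > 0)
    if (k < 2) return(0)
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    s / (k * (k - 1))
  })
  got <- clustering_coefficient(W)
  expect_equal(unname(attr(got, "per_node")), cc_manual, tolerance = 1e-12)
})

test_that("betweenness centrality matches pair enumeration on toys", {
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(unname(betweenness_centrality(P3)), c(0, 1, 0))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(unname(betweenness_centrality(star))[1], 1)
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_true(all(betweenness_centrality(K4) == 0))
  rk <- rank_betweenness(connectivity_matrix(star, "thresholded"))
  expect_equal(rk$node[1], "1")
})

test_that("modularity follows the within-module edge formula", {
  tri2 <- matrix(0, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1
  tri2 <- tri2 + t(tri2)
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)     # one module
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # any partition stays below 1
  set.seed(7)
  for (i in 1:5) {
    A <- rand_adjacency(7, 0.5, seed = i)
    if (sum(A) == 0) next
    expect_lte(modularity_q(A, sample(1:3, 7, TRUE)), 1)
  }
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "no edges")
})

test_that("the modularity maximizer finds exhaustive optima on small graphs", {
  # two disconnected triangles: recovers the components at Q = 0.5
  tri2 <- matrix(0, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1
  tri2 <- tri2 + t(tri2)
  mm <- maximize_modularity(tri2, seed = 1)
  expect_equal(mm$m_max, 0.5)
  expect_equal(mm$partition$n_modules, 2L)
  expect_equal(modularity_q(tri2, mm$partition), mm$m_max)
  # random suite vs exhaustive enumeration
  set.seed(42)
  for (trial in 1:12) {
    n <- sample(4:8, 1)
    A <- rand_adjacency(n, runif(1, 0.2, 0.8), seed = trial + 100)
    if (sum(A) == 0) next
    qs <- vapply(all_partitions(n), function(p) modularity_q(A, p),
                 numeric(1))
    got <- maximize_modularity(A, seed = trial)
    expect_lt(abs(got$m_max - max(qs)), 1e-12)
  }
  # determinism under a fixed seed
  A <- rand_adjacency(12, 0.3, seed = 9)
  expect_identical(maximize_modularity(A, seed = 5),
                   maximize_modularity(A, seed = 5))
})

test_that("the pipeline stages carry their tags in order", {
  set.seed(8)
  im <- intensity_matrix(matrix(runif(40, 1, 2), 8, 5))
  c1 <- correlation_network(im)
  c2 <- standardize_columns(c1)
  c3 <- normalize_and_threshold(c2, 0.2)
  expect_identical(c(c1$stage, c2$stage, c3$stage),
                   c("clipped", "zscored", "thresholded"))
  expect_error(connectivity_matrix(matrix(1, 2, 3), "clipped"), "square")
})
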