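# shared fixtures, all generated in code

# small deterministic random volume
rand_volume <- function(d = c(8, 8, 8), spacing = c(2, 2, 2), seed = 1,
                        lo = 0, hi = 10) {
  set.seed(seed)
  vol_image(array(runif(prod(d), lo, hi), d), spacing)
}

# brute-force spatial convolution with symmetric (reflective) padding —
# the independent oracle for the FFT path
brute_conv3 <- function(arr, kern) {
  d <- dim(arr); kd <- dim(kern); r <- (kd - 1L) %/% 2L
  pad_index <- function(dd, rr) {
    if (rr == 0L) seq_len(dd) else c(rev(seq_len(rr)), seq_len(dd),
                                     dd - seq_len(rr) + 1L)
  }
  ap <- arr[pad_index(d[1], r[1]), pad_index(d[2], r[2]),
            pad_index(d[3], r[3]), drop = FALSE]
  offs <- lapply(1:3, function(a) seq(-r[a], r[a]))
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (a in seq_along(offs[[1]])) for (b in seq_along(offs[[2]]))
      for (cc in seq_along(offs[[3]]))
        s <- s + kern[a, b, cc] *
          ap[i + r[1] - offs[[1]][a],
             j + r[2] - offs[[2]][b],
             k + r[3] - offs[[3]][cc]]
    out[i, j, k] <- s
  }
  out
}

# a tiny two-region 1D-style parcellation on an n x 1 x 1 grid
parc_1d <- function(n = 24, split = 12, spacing = 2) {
  labels <- array(0L, c(n, 1L, 1L))
  labels[2:split, 1, 1] <- 1L
  labels[(split + 1):(n - 1), 1, 1] <- 2L
  structure(list(labels = labels, tissue = NULL,
                 regions = data.frame(label = 1:2,
                                      name = c("left", "right")),
                 spacing = rep(spacing, 3)),
            class = "parcellation")
}

# enumerate all partitions of n items (restricted growth strings) — the
# exhaustive modularity oracle
all_partitions <- function(n) {
  res <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      res[[length(res) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  res
}

# random symmetric binary adjacency matrix
rand_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}
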