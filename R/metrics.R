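as_binary_adjacency <- function(weights) {
  W <- if (inherits(weights, "connectivity_matrix")) weights$weights
       else as.matrix(weights)
  A <- (W != 0) * 1
  diag(A) <- 0
  A
}

as_weight_matrix <- function(weights) {
  W <- if (inherits(weights, "connectivity_matrix")) weights$weights
       else as.matrix(weights)
  diag(W) <- 0
  W
}

graph_from_binary <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Node degrees and network density
#'
#' Binarizes the (thresholded) connectivity matrix, takes row sums as node
#' degrees, and reports the density `d = 2K / (N^2 - N)` with `K` the
#' undirected edge count and `N` the node count taken from the matrix.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @return List with `degree` (vector) and `density` (scalar in `[0, 1]`).
#' @export
degree_and_density <- function(weights) {
  A <- as_binary_adjacency(weights)
  deg <- rowSums(A)
  N <- nrow(A)
  K <- sum(A) / 2
  d <- if (N > 1) 2 * K / (N^2 - N) else 0
  list(degree = deg, density = d)
}

#' Global efficiency
#'
#' Average over ordered node pairs of the inverse binary shortest-path
#' length, with disconnected pairs contributing 0; lies in `[0, 1]`.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(weights) {
  A <- as_binary_adjacency(weights)
  N <- nrow(A)
  if (N < 2) return(0)
  D <- igraph::distances(graph_from_binary(A))
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (N * (N - 1))
}

#' Clustering coefficient
#'
#' Average local clustering. The default weighted-undirected form uses the
#' geometric mean of triangle weights on max-normalized weights
#' (`C_i = [ (W^(1/3))^3 ]_ii / (k_i (k_i - 1))`, `k_i` the binary degree);
#' `type = "binary"` gives the fraction of closed neighbour pairs. Nodes
#' with degree < 2 contribute 0.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @param type `"weighted"` (default) or `"binary"`.
#' @return Scalar average clustering; attribute `"per_node"` carries the
#'   per-node values.
#' @export
clustering_coefficient <- function(weights, type = c("weighted", "binary")) {
  type <- match.arg(type)
  W <- as_weight_matrix(weights)
  A <- as_binary_adjacency(W)
  if (type == "binary") W <- A
  mx <- max(W)
  if (mx > 0) W <- W / mx
  W13 <- W^(1 / 3)
  tri <- diag(W13 %*% W13 %*% W13)
  k <- rowSums(A)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  out <- mean(cc)
  attr(out, "per_node") <- cc
  out
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths on the binarized graph that pass through
#' each node, normalized by the `(N - 1)(N - 2) / 2` node pairs so values
#' lie in `[0, 1]`.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @return Named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(weights) {
  A <- as_binary_adjacency(weights)
  N <- nrow(A)
  if (N < 3) {
    b <- rep(0, N)
  } else {
    b <- igraph::betweenness(graph_from_binary(A), directed = FALSE,
                             weights = NULL)
    b <- b / ((N - 1) * (N - 2) / 2)
  }
  names(b) <- if (inherits(weights, "connectivity_matrix"))
    weights$node_labels else as.character(seq_len(N))
  b
}

#' Rank nodes by betweenness centrality
#'
#' @param weights a thresholded [connectivity_matrix()].
#' @return data.frame with columns `node`, `betweenness`, sorted descending.
#' @export
rank_betweenness <- function(weights) {
  b <- betweenness_centrality(weights)
  data.frame(node = names(b)[order(-b)],
             betweenness = unname(sort(b, decreasing = TRUE)),
             stringsAsFactors = FALSE)
}

#' Node partition into modules
#'
#' @param assignment integer module id per node.
#' @return Object of class `graph_partition` with `assignment` (canonical
#'   1..N ids) and `n_modules`.
#' @export
graph_partition <- function(assignment) {
  assignment <- as.integer(factor(assignment,
                                  levels = unique(assignment)))
  structure(list(assignment = assignment,
                 n_modules = length(unique(assignment))),
            class = "graph_partition")
}

#' Modularity of a partition
#'
#' `Q = sum_i [ p_i / P - (d_i / (2 P))^2 ]` over modules i, with `p_i` the
#' within-module edge count, `d_i` the summed degrees of module i's nodes,
#' and `P` the total edge count, all on the binarized graph.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix).
#' @param partition a [graph_partition()] (or an assignment vector).
#' @return Scalar Q.
#' @export
modularity_q <- function(weights, partition) {
  A <- as_binary_adjacency(weights)
  if (!inherits(partition, "graph_partition"))
    partition <- graph_partition(partition)
  mem <- partition$assignment
  if (length(mem) != nrow(A))
    stop("modularity_q: partition does not cover all nodes")
  P <- sum(A) / 2
  if (P < 1) stop("modularity_q: graph has no edges")
  deg <- rowSums(A)
  same <- outer(mem, mem, `==`)
  p_i_tot <- sum(A[same]) / 2
  d_i <- tapply(deg, mem, sum)
  p_i <- vapply(sort(unique(mem)), function(c0) {
    ix <- mem == c0
    sum(A[ix, ix, drop = FALSE]) / 2
  }, numeric(1))
  sum(p_i / P - (d_i / (2 * P))^2)
}

# Q delta of moving node v from its community to community b (Louvain form)
move_gain <- function(kin_b, kin_a, kv, Dtot_b, Dtot_a, P) {
  (kin_b - kin_a) / P - (kv * (Dtot_b - (Dtot_a - kv)) + kv^2) / (2 * P^2)
}

#' Maximize modularity
#'
#' Greedy modularity maximization on the binarized graph: repeated
#' local node-move passes from a singleton start, alternated with
#' best-pair community merges, over several seed-derived random node
#' orders; the best partition across restarts is returned. Deterministic
#' under a fixed seed.
#'
#' @param weights a thresholded [connectivity_matrix()] (or plain matrix)
#'   with at least one edge.
#' @param seed integer seed for the restart orders.
#' @param restarts number of random restarts (default 8; small graphs get
#'   extra restarts, which are cheap and guard against the shallow local
#'   optima dense little graphs produce).
#' @return List with `partition` (a [graph_partition()]) and `m_max`
#'   (its modularity, equal to `modularity_q(weights, partition)`).
#' @export
maximize_modularity <- function(weights, seed = 1, restarts = 8) {
  A <- as_binary_adjacency(weights)
  n <- nrow(A)
  P <- sum(A) / 2
  if (P < 1) stop("maximize_modularity: graph has no edges")
  if (n <= 12) restarts <- max(restarts, 40L)
  deg <- rowSums(A)

  refine <- function(mem, order_v) {
    repeat {
      moved <- FALSE
      Dtot <- vapply(seq_len(max(mem)), function(c0) sum(deg[mem == c0]),
                     numeric(1))
      for (v in order_v) {
        a <- mem[v]
        nb <- which(A[v, ] > 0)
        if (!length(nb)) next
        # candidate destinations: neighbouring communities plus a fresh
        # singleton community (encoded as 0)
        cand <- unique(mem[nb])
        kin <- vapply(cand, function(c0) sum(A[v, nb[mem[nb] == c0]]),
                      numeric(1))
        cand <- c(cand, 0L)
        kin <- c(kin, 0)
        dt_b <- c(Dtot[cand[-length(cand)]], 0)
        kin_a <- if (a %in% cand) kin[match(a, cand)] else 0
        gains <- move_gain(kin, kin_a, deg[v], dt_b, Dtot[a], P)
        gains[cand == a] <- 0
        best <- which.max(gains)
        if (gains[best] > 1e-13) {
          b <- cand[best]
          if (b == 0L) {
            b <- length(Dtot) + 1L
            Dtot <- c(Dtot, 0)
          }
          Dtot[a] <- Dtot[a] - deg[v]
          Dtot[b] <- Dtot[b] + deg[v]
          mem[v] <- b
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    mem
  }

  merge_pass <- function(mem) {
    repeat {
      cs <- sort(unique(mem))
      if (length(cs) < 2) break
      Dtot <- vapply(cs, function(c0) sum(deg[mem == c0]), numeric(1))
      Ebt <- matrix(0, length(cs), length(cs))
      for (i in seq_along(cs)) for (j in seq_along(cs)) if (i < j)
        Ebt[i, j] <- sum(A[mem == cs[i], mem == cs[j], drop = FALSE])
      gain <- Ebt / P - (Dtot %o% Dtot) / (2 * P^2)
      gain[lower.tri(gain, diag = TRUE)] <- -Inf
      bi <- which.max(gain)
      if (gain[bi] <= 1e-13) break
      ij <- arrayInd(bi, dim(gain))
      mem[mem == cs[ij[2]]] <- cs[ij[1]]
      mem <- as.integer(factor(mem))
    }
    mem
  }

  starts <- with_seed(seed, lapply(seq_len(restarts), function(i) {
    list(order = sample.int(n),
         init = sample.int(sample(2:max(2L, n - 1L), 1), n, replace = TRUE))
  }))
  polish <- function(mem, ord) {
    repeat {
      mem2 <- merge_pass(mem)
      mem2 <- as.integer(factor(refine(mem2, ord)))
      if (modularity_q(A, mem2) > modularity_q(A, mem) + 1e-13)
        mem <- mem2
      else break
    }
    mem
  }
  best_q <- -Inf
  best_mem <- seq_len(n)
  for (st in starts) {
    ord <- st$order
    # move-first (Louvain-like), merge-first (agglomerative) and random
    # initial partitions, each followed by alternating merge/move polish
    inits <- list(move = seq_len(n), merge = seq_len(n),
                  random = as.integer(factor(st$init)))
    for (start in names(inits)) {
      mem <- inits[[start]]
      mem <- if (start == "merge") as.integer(factor(merge_pass(mem)))
             else as.integer(factor(refine(mem, ord)))
      mem <- polish(mem, ord)
      q <- modularity_q(A, mem)
      if (q > best_q + 1e-13) {
        best_q <- q
        best_mem <- mem
      }
    }
  }
  part <- graph_partition(best_mem)
  list(partition = part, m_max = best_q)
}

#' Network metrics report
#'
#' Computes the standard metric panel for one thresholded group network:
#' density D, global efficiency E_global, weighted-undirected clustering
#' C_wu, maximum modularity M_max, plus the degree and betweenness vectors.
#'
#' @param weights a thresholded [connectivity_matrix()].
#' @param seed seed for the modularity maximizer.
#' @param group,condition optional report labels.
#' @return List with `summary` (one-row data.frame with columns `group`,
#'   `condition`, `density`, `e_global`, `c_wu`, `m_max`), `degree`,
#'   `betweenness`, `partition`.
#' @export
network_metrics <- function(weights, seed = 1, group = "group",
                            condition = "pre") {
  dd <- degree_and_density(weights)
  eg <- global_efficiency(weights)
  cw <- as.numeric(clustering_coefficient(weights, "weighted"))
  mm <- maximize_modularity(weights, seed = seed)
  bt <- betweenness_centrality(weights)
  list(summary = data.frame(group = group, condition = condition,
                            density = dd$density, e_global = eg,
                            c_wu = cw, m_max = mm$m_max,
                            stringsAsFactors = FALSE),
       degree = dd$degree, betweenness = bt, partition = mm$partition)
}
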