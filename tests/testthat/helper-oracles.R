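# Independent oracles, deliberately written differently from the package
# internals they cross-check.

# O(T^2) brute-force adjacency: compare every pair of triangles (and every
# pair of vertices within a triangle) for shared edges.
brute_force_adjacency <- function(triangles, n) {
  A <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(triangles))) {
    t3 <- triangles[k, ]
    for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
      i <- t3[pair[1]]; j <- t3[pair[2]]
      A[i, j] <- TRUE; A[j, i] <- TRUE
    }
  }
  A
}

# Recursive flood fill over an adjacency matrix, restricted to `members`.
flood_fill_clusters <- function(members, adj_matrix) {
  remaining <- members
  clusters <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    frontier <- comp
    while (length(frontier)) {
      nxt <- setdiff(which(apply(adj_matrix[frontier, , drop = FALSE], 2, any)),
                     comp)
      frontier <- intersect(nxt, remaining)
      comp <- c(comp, frontier)
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  clusters
}

# Exhaustive sign-flip enumeration for a paired cluster test: returns the
# p value of every observed cluster, computed from scratch with its own t
# statistic and its own flood fill.
enumerate_cluster_p <- function(d, adj_matrix, t_crit) {
  n <- nrow(d)
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  clusters_of <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      sup <- which(sgn * tv > t_crit)
      for (cl in flood_fill_clusters(sup, adj_matrix))
        out[[length(out) + 1L]] <- list(members = cl, sum_t = sum(tv[cl]))
    }
    out
  }
  t_obs <- apply(d, 2, tstat)
  obs <- clusters_of(t_obs)
  null_max <- numeric(2^n)
  for (k in seq_len(2^n)) {
    bits <- as.integer(intToBits(k - 1))[seq_len(n)]
    s <- ifelse(bits == 1, -1, 1)
    tv <- apply(d * s, 2, tstat)
    cls <- clusters_of(tv)
    null_max[k] <- if (length(cls)) max(abs(vapply(cls, `[[`, 1, "sum_t"))) else 0
  }
  vapply(obs, function(cl) mean(null_max >= abs(cl$sum_t) - 1e-12), 1)
}

# Graph distance (BFS) between two vertices given a neighbor list.
graph_distance <- function(neighbors, from, to) {
  dist <- rep(Inf, length(neighbors))
  dist[from] <- 0
  frontier <- from
  while (length(frontier) && !is.finite(dist[to])) {
    nxt <- unique(unlist(neighbors[frontier]))
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  dist[to]
}

adjacency_matrix_of <- function(adj) {
  A <- matrix(FALSE, adj$n, adj$n)
  A[adj$edges] <- TRUE
  A[adj$edges[, c(2, 1), drop = FALSE]] <- TRUE
  A
}
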