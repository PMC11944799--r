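# Independent brute-force implementations of every topology metric,
# written directly from the definitions with plain loops on the
# adjacency matrix.  These act as oracles for topology_summary().

brute_adjacency <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  W <- A
  el <- igraph::as_edgelist(g)
  rs <- igraph::E(g)$r
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    A[i, j] <- A[j, i] <- 1
    W[i, j] <- W[j, i] <- rs[e]
  }
  list(A = A, W = W, r = rs)
}

brute_topology <- function(net, membership, removal_sets) {
  ad <- brute_adjacency(net)
  A <- ad$A; W <- ad$W
  n <- nrow(A)
  e <- sum(A) / 2
  deg <- rowSums(A)
  out <- list(node_num = n, edge_num = e)
  out$average_degree <- 2 * e / n
  out$average_weighted_degree <- mean(rowSums(abs(W)))
  out$density <- 2 * e / (n * (n - 1))

  # shortest paths on the largest connected component (unweighted)
  comp <- brute_components(A)
  big <- which(comp == which.max(tabulate(comp)))
  D <- brute_floyd(A[big, big, drop = FALSE])
  finite <- D[upper.tri(D)]
  out$diameter <- if (length(finite)) max(finite) else NA_real_
  out$average_path_length <- if (length(finite)) mean(finite) else NA_real_

  out$modularity <- brute_modularity(abs(W), membership)
  out$n_communities <- length(unique(membership))

  # local clustering (degree < 2 contributes 0) and global transitivity
  loc <- numeric(n)
  tri2 <- 0; triples <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    d <- length(nb)
    if (d >= 2) {
      links <- sum(A[nb, nb]) / 2
      loc[i] <- links / (d * (d - 1) / 2)
      tri2 <- tri2 + links      # counts each triangle 3x across nodes
      triples <- triples + d * (d - 1) / 2
    }
  }
  out$average_clustering_coefficient <- mean(loc)
  out$transitivity <- if (triples > 0) tri2 / triples else NA_real_

  # degree assortativity: Pearson over edge endpoint degrees, both
  # orientations of every edge
  xs <- c(); ys <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] > 0) {
    xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
  }
  out$assortativity <- if (stats::sd(xs) > 0)
    stats::cor(xs, ys) else NA_real_

  out$degree_centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_

  out$average_neighbors <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) return(NA_real_)
    mean(deg[nb])
  }, numeric(1)), na.rm = TRUE)

  out$frac_positive <- mean(ad$r > 0)
  out$frac_negative <- mean(ad$r < 0)

  out$robustness <- mean(vapply(removal_sets, function(rm) {
    keep <- setdiff(seq_len(n), rm)
    if (!length(keep)) return(0)
    ck <- brute_components(A[keep, keep, drop = FALSE])
    max(tabulate(ck)) / n
  }, numeric(1)))
  out
}

brute_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

brute_floyd <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_modularity <- function(Wabs, membership) {
  m2 <- sum(Wabs)           # 2m
  if (m2 == 0) return(NA_real_)
  s <- rowSums(Wabs)
  q <- 0
  n <- nrow(Wabs)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + Wabs[i, j] - s[i] * s[j] / m2
  unname(q / m2)
}
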