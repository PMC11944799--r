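# Spearman-thresholded co-occurrence networks and their topology.
# An edge joins two OTUs whose abundance profiles across samples have
# |Spearman r| > r_min and p < alpha (strict inequalities); edge weight is
# |r| with the sign stored separately.  Topology metrics follow the usual
# Gephi/igraph conventions; robustness is the mean relative size of the
# largest connected component after random removal of a fixed fraction of
# nodes.

#' Spearman correlation and p-value matrices for an OTU table
#'
#' Correlates OTU abundance profiles across samples (average-rank tie
#' handling).  Two-sided p-values use the t approximation
#' t = r * sqrt((n-2)/(1-r^2)); with the small sample sizes typical of a
#' per-crop subset this is the usual screening convention for
#' all-against-all OTU matrices.  Constant (zero-variance) OTU columns get
#' NA correlations with a single warning.
#'
#' @param t an [otu_table()], normally already prevalence-filtered with
#'   [prevalence_filter_top()].
#' @param min_samples minimum number of samples required.
#' @return List with `r` and `p`: symmetric matrices with unit diagonal /
#'   zero diagonal, OTU ids as dimnames.
#' @export
spearman_matrix <- function(t, min_samples = 4) {
  stopifnot(inherits(t, "rc_otu_table"))
  n <- nrow(t$counts)
  if (n < min_samples)
    stop("need at least ", min_samples, " samples for correlation",
         call. = FALSE)
  x <- t$counts
  const <- apply(x, 2, function(v) max(v) == min(v))
  suppressWarnings(r <- stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant OTU column(s); correlations set NA",
            call. = FALSE)
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(r) <- 1
  diag(p) <- 0
  list(r = r, p = p)
}

#' Network construction configuration
#'
#' @param keep_fraction fraction of OTUs kept by the prevalence filter
#'   before correlation (default 0.8).
#' @param r_min minimum absolute Spearman r for an edge (strict, default
#'   0.60).
#' @param alpha maximum p-value for an edge (strict, default 0.05).
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"`.
#' @return A list of class `rc_network_config`.
#' @export
network_config <- function(keep_fraction = 0.8, r_min = 0.60, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!(r_min > 0 && r_min < 1)) stop("r_min must be in (0,1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0,1]", call. = FALSE)
  structure(list(keep_fraction = keep_fraction, r_min = r_min,
                 alpha = alpha, p_adjust = p_adjust),
            class = "rc_network_config")
}

#' Build a co-occurrence network from correlation matrices
#'
#' Keeps edges with `|r| > r_min` and `p < alpha` (strict, after optional
#' BH adjustment over the upper triangle).  Isolated nodes are dropped:
#' the node set is the set of OTUs incident to at least one retained edge.
#'
#' @param r,p symmetric matrices from [spearman_matrix()].
#' @param cfg a [network_config()].
#' @return An object of class `rc_network`: a list with `graph` (an
#'   undirected igraph with edge attributes `r`, `p`, `weight = |r|`) and
#'   `config`.
#' @export
build_network <- function(r, p, cfg = network_config()) {
  stopifnot(is.matrix(r), is.matrix(p), all(dim(r) == dim(p)))
  ids <- colnames(r)
  if (is.null(ids)) ids <- paste0("OTU", seq_len(ncol(r)))
  ut <- upper.tri(r)
  idx <- which(ut)
  pv <- p[idx]
  if (cfg$p_adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  keep <- which(!is.na(r[idx]) & !is.na(pv) &
                abs(r[idx]) > cfg$r_min & pv < cfg$alpha)
  if (!length(keep)) {
    warning("no correlations pass the thresholds; empty network",
            call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, config = cfg), class = "rc_network"))
  }
  ij <- arrayInd(idx[keep], dim(r))
  ed <- data.frame(from = ids[ij[, 1]], to = ids[ij[, 2]],
                   r = r[idx[keep]], p = pv[keep],
                   stringsAsFactors = FALSE)
  # canonical a < b ordering
  swap <- ed$from > ed$to
  tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  ed$weight <- abs(ed$r)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  structure(list(graph = g, config = cfg), class = "rc_network")
}

as_rc_network <- function(g, cfg = network_config()) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::E(g)$weight) && !is.null(igraph::E(g)$r))
    igraph::E(g)$weight <- abs(igraph::E(g)$r)
  structure(list(graph = g, config = cfg), class = "rc_network")
}

#' @export
print.rc_network <- function(x, ...) {
  cat(sprintf("rc_network: %d nodes, %d edges (|r| > %.2f, p < %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$config$r_min, x$config$alpha))
  invisible(x)
}

#' Node and edge tables of a network
#'
#' @param net a `rc_network`.
#' @param seed seed for the module assignment reported in the node table.
#' @return Data frames: nodes (`otu_id`, `module`, `degree`) or edges
#'   (`otu_a`, `otu_b`, `r`, `p`).
#' @export
network_nodes <- function(net, seed = 1L) {
  g <- net$graph
  if (igraph::vcount(g) == 0)
    return(data.frame(otu_id = character(), module = integer(),
                      degree = integer()))
  mod <- if (!is.null(igraph::V(g)$module)) igraph::V(g)$module
         else detect_modules(net, seed = seed)$membership
  data.frame(otu_id = igraph::V(g)$name,
             module = as.integer(mod),
             degree = as.integer(igraph::degree(g)),
             stringsAsFactors = FALSE)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(otu_a = character(), otu_b = character(),
                      r = numeric(), p = numeric()))
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  ed <- data.frame(otu_a = a, otu_b = b, r = igraph::E(g)$r,
                   p = igraph::E(g)$p, stringsAsFactors = FALSE)
  ed[order(ed$otu_a, ed$otu_b), , drop = FALSE]
}

#' Community detection by Louvain
#'
#' Louvain modularity optimisation on |r| edge weights (resolution 1),
#' seeded for reproducibility.  Isolated single-node components, should
#' the graph contain any, count as their own communities.
#'
#' @param net a `rc_network`.
#' @param seed integer seed.
#' @return List with `membership` (named integer vector), `n_communities`
#'   and `modularity`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- net$graph
  if (igraph::vcount(g) == 0)
    return(list(membership = integer(0), n_communities = 0L,
                modularity = NA_real_))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), igraph::V(g)$name),
       n_communities = length(unique(mem)),
       modularity = igraph::modularity(g, mem,
                                       weights = igraph::E(g)$weight))
}

#' Network robustness to random node removal
#'
#' Removes a fixed fraction of nodes uniformly at random and records the
#' size of the largest connected component relative to the original node
#' count; the robustness score is the mean over replicates.
#'
#' @param net a `rc_network`.
#' @param removal_fraction fraction of nodes removed each replicate
#'   (default 0.5); `floor(removal_fraction * N)` nodes are removed.
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed.
#' @param removal_sets optional list of integer vectors of node indices to
#'   remove (overrides random draws; used for validation).
#' @return Mean relative size of the largest remaining component, in
#'   `[0, 1]`.
#' @export
network_robustness <- function(net, removal_fraction = 0.5, n_reps = 100,
                               seed = 1L, removal_sets = NULL) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 2) stop("robustness needs at least 2 nodes", call. = FALSE)
  if (!(removal_fraction > 0 && removal_fraction < 1))
    stop("removal_fraction must be in (0,1)", call. = FALSE)
  k <- floor(removal_fraction * n)
  if (is.null(removal_sets)) {
    set.seed(seed)
    removal_sets <- replicate(n_reps, sample.int(n, k), simplify = FALSE)
  }
  frac <- vapply(removal_sets, function(rm) {
    h <- igraph::delete_vertices(g, rm)
    if (igraph::vcount(h) == 0) return(0)
    max(igraph::components(h)$csize) / n
  }, numeric(1))
  mean(frac)
}

#' Topology summary of a co-occurrence network
#'
#' Computes the seventeen descriptors commonly tabulated for microbial
#' co-occurrence networks: average degree (2E/N), average weighted degree
#' (mean node strength on |r| weights), diameter and average path length
#' (unweighted, on the largest connected component), density
#' (2E/(N(N-1))), Louvain modularity and number of communities, average
#' local clustering coefficient (nodes of degree < 2 contribute 0), node
#' and edge counts, global transitivity, degree assortativity, Freeman
#' degree centralization, mean neighbour degree averaged over nodes,
#' fractions of positive and negative edges, and robustness
#' ([network_robustness()] defaults).
#'
#' @param net a `rc_network`.
#' @param seed seed for module detection and robustness.
#' @return A one-row data frame of class `rc_topology`.
#' @export
topology_summary <- function(net, seed = 1L) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  out <- list(node_num = n, edge_num = e)
  if (n == 0) {
    nv <- stats::setNames(rep(NA_real_, 15), setdiff(topology_metrics(),
                                                     c("node_num", "edge_num")))
    return(structure(c(out, as.list(nv))[topology_metrics()],
                     class = c("rc_topology", "list")))
  }
  deg <- igraph::degree(g)
  out$average_degree <- 2 * e / n
  out$average_weighted_degree <-
    mean(igraph::strength(g, weights = igraph::E(g)$weight))
  out$density <- if (n > 1) 2 * e / (n * (n - 1)) else 0

  if (n >= 3 && e >= 1) {
    comp <- igraph::components(g)
    lcc <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    out$diameter <- igraph::diameter(lcc, weights = NA)
    out$average_path_length <- igraph::mean_distance(lcc, weights = NA)
  } else {
    out$diameter <- NA_real_
    out$average_path_length <- NA_real_
  }

  if (e >= 1) {
    mods <- detect_modules(net, seed = seed)
    out$modularity <- mods$modularity
    out$n_communities <- mods$n_communities
  } else {
    out$modularity <- NA_real_
    out$n_communities <- n
  }

  if (n >= 3) {
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    out$average_clustering_coefficient <- mean(loc)
    tr <- igraph::transitivity(g, type = "global")
    out$transitivity <- ifelse(is.nan(tr), NA_real_, tr)
  } else {
    out$average_clustering_coefficient <- NA_real_
    out$transitivity <- NA_real_
  }

  out$assortativity <- if (e >= 2 && stats::sd(deg) > 0)
    igraph::assortativity_degree(g, directed = FALSE) else NA_real_
  out$degree_centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_

  knn <- if (e >= 1) igraph::knn(g, weights = NA)$knn else rep(NA_real_, n)
  out$average_neighbors <- mean(knn, na.rm = TRUE)

  if (e >= 1 && !is.null(igraph::E(g)$r)) {
    out$frac_positive <- mean(igraph::E(g)$r > 0)
    out$frac_negative <- mean(igraph::E(g)$r < 0)
  } else {
    out$frac_positive <- NA_real_
    out$frac_negative <- NA_real_
  }

  out$robustness <- if (n >= 2)
    network_robustness(net, seed = seed) else NA_real_

  structure(out[topology_metrics()], class = c("rc_topology", "list"))
}

#' @rdname topology_summary
#' @return `topology_metrics()`: the metric names in canonical order.
#' @export
topology_metrics <- function() {
  c("average_degree", "average_weighted_degree", "diameter",
    "average_path_length", "density", "modularity", "n_communities",
    "average_clustering_coefficient", "node_num", "edge_num",
    "transitivity", "assortativity", "degree_centralization",
    "average_neighbors", "frac_positive", "frac_negative", "robustness")
}

#' @export
print.rc_topology <- function(x, ...) {
  df <- data.frame(metric = names(x),
                   value = unlist(lapply(x, function(v)
                     if (is.numeric(v)) round(v, 4) else v)))
  print(df, row.names = FALSE)
  invisible(x)
}
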