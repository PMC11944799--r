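test_that("Spearman matrices follow the rank-correlation definition", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 9, 16, 30, 33),
             c = c(6, 5, 4, 3, 2, 1))
  t <- tiny_otu(m)
  sp <- spearman_matrix(t)
  expect_equal(sp$r["a", "b"], 1)
  expect_equal(sp$r["a", "c"], -1)
  expect_equal(sp$p["a", "b"], 0)
  # tie-free n = 6 fixture against 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3, 1, 6, 2, 5, 4); y <- c(2, 3, 6, 1, 4, 5)
  t2 <- tiny_otu(cbind(x = x, y = y))
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman_matrix(t2)$r["x", "y"], 1 - 6 * d2 / (6 * 35))
})

test_that("constant OTU columns yield missing correlations", {
  t <- tiny_otu(cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(4, 3, 2, 1)))
  expect_warning(sp <- spearman_matrix(t), "constant")
  expect_true(is.na(sp$r["a", "b"]))
  expect_false(is.na(sp$r["a", "c"]))
  expect_error(spearman_matrix(tiny_otu(matrix(1:6, 3))), "at least")
})

test_that("edges require both threshold conditions, strictly", {
  mk <- function(r12, p12) {
    r <- diag(3); r[1, 2] <- r[2, 1] <- r12
    r[1, 3] <- r[3, 1] <- 0.99; r[2, 3] <- r[3, 2] <- 0.1
    p <- matrix(0.5, 3, 3); diag(p) <- 0
    p[1, 2] <- p[2, 1] <- p12
    p[1, 3] <- p[3, 1] <- 0.001
    dimnames(r) <- dimnames(p) <- list(letters[1:3], letters[1:3])
    build_network(r, p)
  }
  expect_equal(nrow(network_edges(mk(0.61, 0.01))), 2)
  expect_equal(nrow(network_edges(mk(0.61, 0.06))), 1)
  expect_equal(nrow(network_edges(mk(0.60, 0.01))), 1)  # strict |r| > 0.6
  ed <- network_edges(mk(0.61, 0.01))
  expect_true(all(ed$otu_a < ed$otu_b))
})

test_that("edge count decreases monotonically with the r threshold", {
  t <- random_otu(17, n_samples = 8, n_otus = 25)
  sp <- spearman_matrix(t)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(rmin)
    nrow(network_edges(suppressWarnings(
      build_network(sp$r, sp$p, network_config(r_min = rmin))))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("isolated nodes are dropped and empty networks warned about", {
  r <- diag(4); r[1, 2] <- r[2, 1] <- 0.9
  p <- matrix(1, 4, 4); p[1, 2] <- p[2, 1] <- 0.01; diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(letters[1:4], letters[1:4])
  net <- build_network(r, p)
  expect_equal(igraph::vcount(net$graph), 2)
  p[1, 2] <- p[2, 1] <- 0.9
  expect_warning(net0 <- build_network(r, p), "empty")
  expect_equal(igraph::vcount(net0$graph), 0)
})

test_that("triangle topology takes its closed-form values", {
  r <- matrix(c(1, .9, -.7, .9, 1, .8, -.7, .8, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(0.01, 3, 3); diag(p) <- 0
  ts <- topology_summary(build_network(r, p))
  expect_equal(ts$transitivity, 1)
  expect_equal(ts$average_clustering_coefficient, 1)
  expect_equal(ts$density, 1)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$frac_positive, 2 / 3)
  expect_equal(ts$n_communities, 1)
})

test_that("degree/density identities hold on random built networks", {
  for (seed in 1:15) {
    net <- random_net(seed, n = 14, p_edge = 0.3)
    ts <- topology_summary(net)
    expect_equal(ts$average_degree * ts$node_num, 2 * ts$edge_num)
    expect_equal(ts$density * (ts$node_num - 1), ts$average_degree)
    expect_equal(ts$frac_positive + ts$frac_negative, 1)
  }
})

test_that("robustness matches analytic cases and removal ordering", {
  full <- igraph::make_full_graph(20)
  igraph::V(full)$name <- paste0("n", 1:20)
  igraph::E(full)$r <- 0.8; igraph::E(full)$weight <- 0.8
  netf <- rarecycle:::as_rc_network(full)
  expect_equal(network_robustness(netf, 0.5, n_reps = 20, seed = 1), 0.5)
  star <- igraph::make_star(20, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:20)
  igraph::E(star)$r <- 0.8; igraph::E(star)$weight <- 0.8
  nets <- rarecycle:::as_rc_network(star)
  expect_lt(network_robustness(nets, 0.5, n_reps = 100, seed = 2),
            network_robustness(netf, 0.5, n_reps = 100, seed = 2))
  # non-increasing in the removal fraction
  net <- random_net(5, n = 15, p_edge = 0.4)
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8), function(fr)
    network_robustness(net, fr, n_reps = 60, seed = 3), numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_error(network_robustness(net, 1.5), "removal_fraction")
})

test_that("module detection separates planted communities", {
  cl <- igraph::make_full_graph(6)
  g <- igraph::disjoint_union(cl, cl)
  igraph::V(g)$name <- paste0("n", 1:12)
  igraph::E(g)$r <- 0.9; igraph::E(g)$weight <- 0.9
  net <- rarecycle:::as_rc_network(g)
  mods <- detect_modules(net, seed = 4)
  expect_equal(mods$n_communities, 2)
  expect_gt(mods$modularity, 0.3)
  expect_identical(mods$membership, detect_modules(net, seed = 4)$membership)
  one <- detect_modules(rarecycle:::as_rc_network(
    igraph::set_edge_attr(igraph::set_vertex_attr(
      igraph::make_full_graph(5), "name", value = letters[1:5]),
      "weight", value = 1)), seed = 1)
  expect_equal(one$n_communities, 1)
})

test_that("an exported network reproduces its topology after re-import", {
  net <- random_net(23, n = 15, p_edge = 0.35)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path)
  net2 <- read_network(path)
  t1 <- topology_summary(net, seed = 5)
  t2 <- topology_summary(net2, seed = 5)
  expect_equal(unclass(t2)[setdiff(topology_metrics(), "robustness")],
               unclass(t1)[setdiff(topology_metrics(), "robustness")],
               tolerance = 1e-10)
})
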