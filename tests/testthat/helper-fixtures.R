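# Small programmatic fixtures shared across test files.

tiny_otu <- function(counts, crop = NULL, taxonomy = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("o", seq_len(ncol(counts)))
  if (is.null(crop)) crop <- rep("crop1", nrow(counts))
  otu_table(counts, crop = crop, taxonomy = taxonomy)
}

random_otu <- function(seed, n_samples = 6, n_otus = 20, crops = NULL,
                       lambda = 40) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  m[1, ] <- m[1, ] + 1  # guard against all-zero samples
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("o%03d", seq_len(n_otus))
  if (is.null(crops))
    crops <- rep(c("a", "b"), length.out = n_samples)
  tax <- paste0("d__X;p__P", sample(1:4, n_otus, replace = TRUE))
  otu_table(m, crop = crops, taxonomy = tax)
}

# random signed weighted graph as an rc_network (for topology tests)
random_net <- function(seed, n = 10, p_edge = 0.4) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  ed <- pairs[keep, , drop = FALSE]
  r <- stats::runif(nrow(ed), 0.6, 1) *
    sample(c(-1, 1), nrow(ed), replace = TRUE)
  df <- data.frame(from = ids[ed[, 1]], to = ids[ed[, 2]],
                   r = r, p = stats::runif(nrow(ed), 0, 0.05),
                   weight = abs(r))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  rarecycle:::as_rc_network(g)
}

default_nutrient_fixture <- function(n = 6) {
  data.frame(sample_id = sprintf("s%02d", 1:n),
             crop = rep(c("a", "b"), length.out = n),
             pH = seq(7.5, 8.5, length.out = n),
             salt = seq(0.5, 1.5, length.out = n),
             BD = seq(1.3, 1.5, length.out = n),
             SWC = seq(10, 20, length.out = n),
             NH4_N = seq(1, 3, length.out = n),
             NO3_N = seq(40, 100, length.out = n),
             Olsen_P = seq(10, 30, length.out = n),
             Avail_K = seq(110, 160, length.out = n),
             AN = seq(0.05, 0.1, length.out = n),
             TP = seq(2.5, 3.2, length.out = n),
             TK = seq(14, 25, length.out = n),
             TN = seq(1.4, 6.3, length.out = n),
             SOC = seq(5.5, 9, length.out = n),
             stringsAsFactors = FALSE)
}
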