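test_that("relative abundance normalises rows exactly", {
  t <- tiny_otu(matrix(c(10, 30, 60), 1))
  expect_equal(as.numeric(relative_abundance(t)), c(0.1, 0.3, 0.6))
  t1 <- tiny_otu(matrix(c(7, 3), 2, 1))
  expect_equal(as.numeric(relative_abundance(t1)), c(1, 1))
  t2 <- random_otu(3, n_samples = 20, n_otus = 50)
  expect_equal(unname(rowSums(relative_abundance(t2))), rep(1, 20),
               tolerance = 1e-12)
})

test_that("zero-total samples are reported by name", {
  m <- matrix(c(5, 5, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("good", "empty"), c("o1", "o2")))
  t <- otu_table(m, crop = c("a", "a"))
  expect_error(relative_abundance(t), "empty")
})

test_that("classification respects the abundance thresholds", {
  # mean relative abundances: 0.001 (abundant), 5e-6 (rare), 1e-4
  # (intermediate), remainder absorbed by a filler OTU
  n <- 1e6
  counts <- matrix(c(0.001 * n, 5 * 1, 100 * 1,
                     n - 0.001 * n - 5 - 100), 1)
  counts <- rbind(counts, counts)
  t <- tiny_otu(counts)
  cls <- classify_taxa(t)
  expect_equal(as.character(cls$class[1:3]),
               c("abundant", "rare", "intermediate"))
  expect_equal(sum(cls$counts), ncol(t$counts))
  expect_error(classify_taxa(t, rare_max = 0.01, abundant_min = 0.001),
               "smaller")
})

test_that("classification is invariant to per-sample rescaling", {
  t <- random_otu(7, n_samples = 5, n_otus = 30)
  cls1 <- classify_taxa(t, rare_max = 0.01, abundant_min = 0.05)
  t$counts[2, ] <- t$counts[2, ] * 7
  cls2 <- classify_taxa(t, rare_max = 0.01, abundant_min = 0.05)
  expect_identical(cls1$class, cls2$class)
})

test_that("class subsets keep samples and counts untouched", {
  n <- 1e6
  m <- matrix(rep(c(2000, 3000, 1, 2, 3, n - 5006), 2), 2,
              byrow = TRUE)
  t <- tiny_otu(m)
  cls <- classify_taxa(t, rare_max = 1e-5, abundant_min = 5e-4)
  rare <- subset_by_class(t, cls, "rare")
  expect_equal(ncol(rare$counts), 3)
  expect_equal(nrow(rare$counts), 2)
  expect_equal(colSums(rare$counts),
               colSums(t$counts)[colnames(rare$counts)])
  ab <- subset_by_class(t, cls, "abundant")
  expect_equal(ncol(ab$counts), 3)
  all_rare <- tiny_otu(matrix(rep(1, 8), 2))
  cls2 <- classify_taxa(all_rare, rare_max = 0.5, abundant_min = 0.9)
  expect_error(subset_by_class(all_rare, cls2, "abundant"), "threshold")
})

test_that("the top-fraction prevalence filter ranks by mean abundance", {
  t <- random_otu(9, n_samples = 4, n_otus = 10)
  expect_equal(ncol(prevalence_filter_top(t, 0.8)$counts), 8)
  expect_identical(prevalence_filter_top(t, 1)$counts, t$counts)
  m <- matrix(rep(c(5, 4, 3, 2, 1), 2), 2, byrow = TRUE) * 100
  t5 <- tiny_otu(m)
  kept <- prevalence_filter_top(t5, 0.8)
  expect_setequal(otu_ids(kept), c("o1", "o2", "o3", "o4"))
  # ties broken lexicographically by OTU id
  tt <- tiny_otu(matrix(c(1, 1, 1), 1))
  expect_setequal(otu_ids(prevalence_filter_top(tt, 0.5)),
                  c("o1", "o2"))
})

test_that("phylum aggregation conserves abundance and pools the tail", {
  t <- tiny_otu(matrix(c(40, 60), 1),
                taxonomy = c("d__B;p__Actinobacteria",
                             "d__B;p__Actinobacteria"))
  pa <- phylum_aggregate(t)
  expect_equal(unname(pa$fractions["Actinobacteria", 1]), 1)

  t2 <- random_otu(13, n_samples = 5, n_otus = 36)
  t2$taxonomy[] <- paste0("d__X;p__Ph", rep(1:12, 3))
  pa2 <- phylum_aggregate(t2)
  expect_equal(unname(colSums(pa2$fractions)), rep(1, 5),
               tolerance = 1e-12)
  expect_equal(nrow(pa2$top), 11)  # 10 phyla + Other
  expect_true("Other" %in% rownames(pa2$top))
})

test_that("unparseable lineages fall back to unclassified", {
  expect_equal(extract_phylum(c("d__B;p__Chloroflexi", "unclassified",
                                "Bacteria;Firmicutes;Bacilli", "")),
               c("Chloroflexi", "unclassified", "Firmicutes",
                 "unclassified"))
})

test_that("OTU overlap counts match brute-force set algebra", {
  t1 <- tiny_otu(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE),
                 crop = c("A", "B"))
  ov <- otu_overlap(split_by_crop(t1))
  expect_equal(unname(ov$unique[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(ov$intersections[["A+B"]]), 1L)

  same <- otu_overlap(list(g1 = tiny_otu(matrix(1:4, 1)),
                           g2 = tiny_otu(matrix(1:4, 1))))
  expect_equal(unname(same$intersections[["g1+g2"]]), 4L)
  expect_equal(unname(same$unique), c(0L, 0L))

  # random 4-group fixture against direct set computation
  set.seed(42)
  groups <- lapply(1:4, function(i) {
    m <- matrix(rbinom(30, 1, 0.5) * rpois(30, 5), 3, 10)
    colnames(m) <- sprintf("o%02d", 1:10)
    tiny_otu(m)
  })
  names(groups) <- paste0("g", 1:4)
  ov4 <- otu_overlap(groups)
  sets <- lapply(groups, function(t) colnames(t$counts)[colSums(t$counts) > 0])
  for (pat in names(ov4$intersections)) {
    inc <- strsplit(pat, "+", fixed = TRUE)[[1]]
    exc <- setdiff(names(sets), inc)
    members <- Reduce(intersect, sets[inc])
    for (g in exc) members <- setdiff(members, sets[[g]])
    expect_equal(unname(ov4$intersections[[pat]]), length(members))
  }
  expect_error(otu_overlap(groups[1]), "at least 2")
})
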