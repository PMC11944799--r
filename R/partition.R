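# Rare/abundant taxa partitioning.  An OTU is "abundant" when its mean
# relative abundance across all samples exceeds 0.05% and "rare" when it
# is below 0.001%; OTUs between the two thresholds are "intermediate" and
# belong to neither sub-community.

#' Relative abundance matrix
#'
#' @param t an [otu_table()].
#' @return Numeric matrix of per-sample relative abundances (rows sum
#'   to 1), same shape and dimnames as the counts.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "rc_otu_table"))
  tot <- rowSums(t$counts)
  bad <- which(tot == 0)
  if (length(bad))
    stop("zero total count in sample(s): ",
         paste(rownames(t$counts)[bad], collapse = ", "), call. = FALSE)
  sweep(t$counts, 1, tot, "/")
}

#' Classify OTUs into rare / intermediate / abundant taxa
#'
#' Classification is by mean relative abundance across samples:
#' abundant when above `abundant_min` (default 5e-4, i.e. 0.05%), rare
#' when below `rare_max` (default 1e-5, i.e. 0.001%), otherwise
#' intermediate.  Both comparisons are strict, so the classes are
#' exhaustive and exclusive.
#'
#' @param t an [otu_table()].
#' @param rare_max upper relative-abundance bound for rare taxa.
#' @param abundant_min lower relative-abundance bound for abundant taxa.
#' @return An object of class `rc_abundance_class`: list with `class`
#'   (named factor rare/intermediate/abundant per OTU),
#'   `mean_rel_abund`, `thresholds` and `counts` (table of class sizes).
#' @export
classify_taxa <- function(t, rare_max = 1e-5, abundant_min = 5e-4) {
  if (rare_max >= abundant_min)
    stop("rare_max must be smaller than abundant_min", call. = FALSE)
  mra <- colMeans(relative_abundance(t))
  cls <- ifelse(mra > abundant_min, "abundant",
                ifelse(mra < rare_max, "rare", "intermediate"))
  cls <- factor(cls, levels = c("rare", "intermediate", "abundant"))
  names(cls) <- names(mra)
  structure(list(class = cls, mean_rel_abund = mra,
                 thresholds = c(rare_max = rare_max,
                                abundant_min = abundant_min),
                 counts = table(cls)),
            class = "rc_abundance_class")
}

#' @export
print.rc_abundance_class <- function(x, ...) {
  cat(sprintf("taxa classification (rare < %g, abundant > %g):\n",
              x$thresholds["rare_max"], x$thresholds["abundant_min"]))
  print(x$counts)
  invisible(x)
}

#' Subset an OTU table to one abundance class
#'
#' Column subset only: samples and counts are untouched (no
#' renormalisation), so downstream diversity is computed on the raw
#' sub-community counts.
#'
#' @param t an [otu_table()].
#' @param cls an `rc_abundance_class` computed from the same table.
#' @param which `"rare"` or `"abundant"`.
#' @return An [otu_table()] restricted to the chosen class.
#' @export
subset_by_class <- function(t, cls, which = c("rare", "abundant")) {
  which <- match.arg(which)
  stopifnot(inherits(cls, "rc_abundance_class"))
  if (!setequal(names(cls$class), otu_ids(t)))
    stop("classification does not match this OTU table", call. = FALSE)
  keep <- names(cls$class)[cls$class == which]
  if (!length(keep))
    stop("no ", which, " OTUs under the current thresholds; ",
         "review rare_max/abundant_min", call. = FALSE)
  subset_otu_table(t, otus = keep)
}

#' Keep the top fraction of OTUs by mean relative abundance
#'
#' Ranks OTUs by mean relative abundance (descending, ties broken by OTU
#' id) and keeps the top `ceiling(keep_fraction * n_otus)` identities.
#' This is the pre-filter applied before network construction.
#'
#' @param t an [otu_table()].
#' @param keep_fraction fraction of OTU identities to keep (default 0.8).
#' @return An [otu_table()] with the retained OTUs, in original column
#'   order.
#' @export
prevalence_filter_top <- function(t, keep_fraction = 0.8) {
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0,1]", call. = FALSE)
  mra <- colMeans(relative_abundance(t))
  ord <- order(-mra, names(mra))
  n_keep <- ceiling(keep_fraction * length(mra))
  keep <- sort(ord[seq_len(n_keep)])
  subset_otu_table(t, otus = keep)
}

#' Extract the phylum token from a lineage string
#'
#' Understands `p__Phylum` prefixes (Greengenes/QIIME style) and plain
#' semicolon-delimited ranks (second field); unparseable lineages map to
#' `"unclassified"`.
#'
#' @param lineage character vector of taxonomy strings.
#' @return Character vector of phylum names.
#' @export
extract_phylum <- function(lineage) {
  out <- rep("unclassified", length(lineage))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    pp <- trimws(parts[[i]])
    hit <- grep("^p__", pp, value = TRUE)
    if (length(hit)) {
      ph <- sub("^p__", "", hit[1])
      if (nzchar(ph)) out[i] <- ph
    } else if (length(pp) >= 2 && nzchar(pp[2])) {
      out[i] <- pp[2]
    }
  }
  out
}

#' Phylum-level relative abundance
#'
#' Aggregates OTU relative abundances by phylum.  Reports the full
#' phylum x sample fraction matrix plus a display matrix with the `top_k`
#' phyla by overall mean abundance and the remainder pooled as
#' `"Other"`.
#'
#' @param t an [otu_table()].
#' @param top_k number of phyla to report individually (default 10).
#' @return List with `fractions` (phylum x sample matrix, columns sum to
#'   1), `top` (top_k + Other matrix) and `top_phyla` (character).
#' @export
phylum_aggregate <- function(t, top_k = 10) {
  ra <- relative_abundance(t)
  phy <- extract_phylum(t$taxonomy[colnames(ra)])
  agg <- rowsum(base::t(ra), group = phy)  # phylum x sample
  ord <- order(-rowMeans(agg))
  agg <- agg[ord, , drop = FALSE]
  top_phyla <- rownames(agg)[seq_len(min(top_k, nrow(agg)))]
  if (nrow(agg) > length(top_phyla)) {
    other <- colSums(agg[setdiff(rownames(agg), top_phyla), , drop = FALSE])
    top <- rbind(agg[top_phyla, , drop = FALSE], Other = other)
  } else {
    top <- agg
  }
  list(fractions = agg, top = top, top_phyla = top_phyla)
}

#' OTU overlap between groups (Venn / UpSet counts)
#'
#' An OTU is present in a group when its total count there is positive.
#' Returns per-group presence totals, per-group unique counts, and the
#' sizes of all `2^k - 1` exclusive membership patterns (UpSet-style).
#'
#' @param tables named list of [otu_table()]s (>= 2), one per group, or a
#'   single table which is split by its crop labels.
#' @return List with `totals`, `unique`, and `intersections` (named
#'   integer vector; names are `+`-joined group subsets), plus
#'   `presence` (logical OTU x group matrix).
#' @export
otu_overlap <- function(tables) {
  if (inherits(tables, "rc_otu_table"))
    tables <- split_by_crop(tables)
  if (length(tables) < 2)
    stop("otu_overlap needs at least 2 groups", call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("groups must be named", call. = FALSE)
  present <- lapply(tables, function(t) {
    stopifnot(inherits(t, "rc_otu_table"))
    otu_ids(t)[colSums(t$counts) > 0]
  })
  all_otus <- sort(unique(unlist(present)))
  pm <- vapply(present, function(s) all_otus %in% s,
               logical(length(all_otus)))
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = length(all_otus))
  rownames(pm) <- all_otus
  colnames(pm) <- names(tables)
  pattern <- apply(pm, 1, function(z)
    paste(colnames(pm)[z], collapse = "+"))
  k <- length(tables)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(tables), m, paste, collapse = "+",
                 simplify = FALSE)), use.names = FALSE)
  inter <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  inter[names(tab)] <- as.integer(tab)
  uniq <- stats::setNames(inter[names(tables)], names(tables))
  list(totals = vapply(present, length, integer(1)),
       unique = uniq, intersections = inter, presence = pm)
}

#' Split an OTU table by crop label
#'
#' @param t an [otu_table()].
#' @return Named list of per-crop [otu_table()]s.
#' @export
split_by_crop <- function(t) {
  stopifnot(inherits(t, "rc_otu_table"))
  crops <- sort(unique(t$crop))
  stats::setNames(lapply(crops, function(cr)
    subset_otu_table(t, samples = names(t$crop)[t$crop == cr])), crops)
}
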