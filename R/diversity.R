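# Alpha/beta diversity, ordination and the group-comparison /
# matrix-correlation statistics.  Standard computations (Shannon,
# Bray-Curtis, NMDS, PERMANOVA, Mantel) are delegated to vegan, the
# package the field uses for exactly these steps; this module fixes the
# conventions (natural-log Shannon, relative-abundance input, permutation
# counts) and returns uniform result records.

#' Alpha diversity profile
#'
#' Richness is the number of OTUs with positive count; Shannon is
#' computed on relative abundances in nats (0*ln 0 := 0); Pielou evenness
#' is Shannon / ln(richness), defined as 0 for single-OTU samples.  The
#' natural log is what makes the Pielou = Shannon / ln(richness)
#' identity hold for reported index triples.
#'
#' @param t an [otu_table()].
#' @return Data frame with `sample_id`, `crop`, `richness`, `shannon`,
#'   `pielou`.
#' @export
alpha_diversity <- function(t) {
  ra <- relative_abundance(t)
  richness <- rowSums(t$counts > 0)
  shannon <- vegan::diversity(ra, index = "shannon", base = exp(1))
  pielou <- ifelse(richness > 1, shannon / log(richness), 0)
  data.frame(sample_id = rownames(ra), crop = unname(t$crop[rownames(ra)]),
             richness = as.integer(richness), shannon = unname(shannon),
             pielou = unname(pielou), stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed on relative
#' abundances, so entries lie in [0, 1].
#'
#' @param t an [otu_table()].
#' @return A square symmetric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(t) {
  ra <- relative_abundance(t)
  as.matrix(vegan::vegdist(ra, method = "bray"))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS (vegan's monoMDS engine via [vegan::metaMDS()]),
#' best of `n_starts` random starts, deterministic under `seed`.
#'
#' @param d square dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k number of axes (default 2).
#' @param n_starts random starts (default 20).
#' @param max_iter iterations per start.
#' @param seed integer seed.
#' @return List with `points` (n x k coordinate matrix) and `stress`
#'   (Kruskal stress-1, in [0, 1]).
#' @export
run_nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, seed = 1L) {
  d <- as.matrix(d)
  if (nrow(d) < k + 1) stop("need at least k+1 samples", call. = FALSE)
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                        trymax = n_starts, maxit = max_iter,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  pts <- fit$points
  rownames(pts) <- rownames(d)
  list(points = pts, stress = fit$stress, converged = fit$converged > 0)
}

perm_result <- function(statistic, p_value, n_permutations,
                        effect = NA_real_, method = "") {
  structure(list(statistic = statistic, effect = effect,
                 p_value = p_value, n_permutations = n_permutations,
                 method = method),
            class = "rc_perm_test")
}

#' @export
print.rc_perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g (%d permutations)\n",
              x$method, x$statistic,
              if (!is.na(x$effect)) sprintf(", R2 = %.4f", x$effect) else "",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-factor permutational multivariate analysis of variance
#' (Anderson's pseudo-F from partitioned squared dissimilarities), with
#' free permutation of group labels; p = (1 + #{F_perm >= F_obs}) /
#' (n_perm + 1).  Delegates to [vegan::adonis2()].
#'
#' @param d square dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each n >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return An `rc_perm_test` with pseudo-F statistic, `effect` = R
#'   squared, and p-value.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d))
    stop("one group label per sample required", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2)
    stop("PERMANOVA needs at least 2 groups", call. = FALSE)
  if (any(table(droplevels(groups)) < 2))
    stop("every group needs at least 2 samples", call. = FALSE)
  set.seed(seed)
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g, data = df,
                        permutations = n_perm)
  perm_result(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
              n_permutations = n_perm, effect = fit$R2[1],
              method = "PERMANOVA")
}

#' Mantel test between two dissimilarity matrices
#'
#' Correlation of the lower-triangle entries, significance by
#' simultaneous row/column permutation of the second matrix
#' ([vegan::mantel()]).
#'
#' @param d1,d2 square dissimilarity matrices on the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return An `rc_perm_test` with Mantel r and p-value.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stop("dissimilarity matrices must match in size", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("sample ids of the two matrices differ", call. = FALSE)
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       method = method, permutations = n_perm)
  perm_result(statistic = fit$statistic, p_value = fit$signif,
              n_permutations = n_perm, method = "Mantel")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom ([stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return An `rc_perm_test` (the `n_permutations` field is `NA`: the
#'   reference distribution is asymptotic).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  if (length(values) <= nlevels(droplevels(groups)))
    stop("insufficient observations for Kruskal-Wallis", call. = FALSE)
  if (max(values) == min(values))
    return(perm_result(0, 1, NA_integer_, method = "Kruskal-Wallis"))
  fit <- stats::kruskal.test(values, groups)
  perm_result(statistic = unname(fit$statistic),
              p_value = fit$p.value, n_permutations = NA_integer_,
              method = "Kruskal-Wallis")
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Classic Duncan procedure: one-way ANOVA MSE; ordered means compared
#' with the least significant studentized range at Duncan's protection
#' levels, i.e. the critical value for a span of p means is
#' qtukey((1 - alpha)^(p - 1), p, df_error) * sqrt(MSE / n_h) with n_h
#' the harmonic mean group size.  A range contained in a non-significant
#' range is itself declared non-significant, and groups are reported as
#' connected letters sorted by descending mean.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups with >= 2 replicates).
#' @param alpha significance level (default 0.05).
#' @return Data frame with `group`, `mean`, `n`, `letters`, sorted by
#'   descending mean; attributes `MSE`, `df_error`, `F`, `p_value`.
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("Duncan's test needs at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 replicates", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  mse <- an$`Mean Sq`[2]
  dfe <- an$Df[2]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  n_h <- k / sum(1 / ns)
  ord <- order(-means)
  m <- means[ord]

  # significance of the range spanning sorted means i..j
  sig <- matrix(FALSE, k, k)
  if (mse > 0) {
    for (span in 2:k) {
      q <- stats::qtukey((1 - alpha)^(span - 1), span, dfe)
      lsr <- q * sqrt(mse / n_h)
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        sig[i, j] <- (m[i] - m[j]) > lsr
      }
    }
    # protection: a range inside a non-significant wider range is ns
    for (span in seq(k - 1, 2)) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        wider_ns <- (i > 1 && !sig[i - 1, j]) || (j < k && !sig[i, j + 1])
        if (sig[i, j] && wider_ns) sig[i, j] <- FALSE
      }
    }
  } else {
    for (i in seq_len(k)) for (j in seq_len(k))
      if (j > i) sig[i, j] <- m[i] != m[j]
  }

  # maximal runs of mutually non-significant sorted means -> letters
  ends <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    as.integer(j)
  }, integer(1))
  starts <- seq_len(k)
  maximal <- !vapply(seq_len(k), function(i)
    any(starts < i & ends >= ends[i]), logical(1))
  runs <- lapply(which(maximal), function(i) starts[i]:ends[i])
  lett <- rep("", k)
  for (r in seq_along(runs))
    lett[runs[[r]]] <- paste0(lett[runs[[r]]], letters[r])

  out <- data.frame(group = names(m), mean = unname(m),
                    n = as.integer(ns[names(m)]), letters = lett,
                    stringsAsFactors = FALSE)
  attr(out, "MSE") <- mse
  attr(out, "df_error") <- dfe
  attr(out, "F") <- an$`F value`[1]
  attr(out, "p_value") <- an$`Pr(>F)`[1]
  out
}

#' Pairwise correlation screen between two variable tables
#'
#' Every column of `x_table` against every column of `y_table`, Pearson
#' or Spearman, with two-sided p-values from [stats::cor.test()] (t
#' approximation for Pearson; for Spearman the exact null distribution
#' when n <= 10 and tie-free, otherwise the t approximation).  Constant
#' columns yield missing correlations with a warning.
#'
#' @param x_table,y_table data frames or matrices with matched rows
#'   (samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return Long-format data frame `x`, `y`, `r`, `p`.
#' @export
correlation_screen <- function(x_table, y_table,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.data.frame(x_table)
  y <- as.data.frame(y_table)
  if (nrow(x) != nrow(y))
    stop("x_table and y_table must have matched samples", call. = FALSE)
  n <- nrow(x)
  if (n <= 10 && method == "spearman") exact <- TRUE else exact <- NULL
  out <- expand.grid(x = names(x), y = names(y), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  warned <- FALSE
  for (i in seq_len(nrow(out))) {
    xv <- x[[out$x[i]]]; yv <- y[[out$y[i]]]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      warned <- TRUE
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(xv, yv, method = method, exact = exact))
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  if (warned)
    warning("constant column(s): correlations reported as missing",
            call. = FALSE)
  out
}
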