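# The causal / importance layer: a recursive path model linking soil
# salinity, rare/abundant Shannon diversity and the multi-nutrient
# cycling index, plus random-forest permutation importance of nutrient
# variables for rare-taxa diversity.

#' Path model specification
#'
#' A directed acyclic set of edges among observed variables.  The default
#' mirrors the study layout: salinity points at the four sub-community
#' Shannon indices (rare/abundant x bacteria/fungi), and those four plus
#' salinity point at the MNC.
#'
#' @param edges data frame with columns `from`, `to`.
#' @param include_salt_mnc keep the direct salinity -> MNC path in the
#'   default spec (default `TRUE`).
#' @return A validated object of class `rc_path_spec` with the variables
#'   in a topological order.
#' @export
path_model_spec <- function(edges = NULL, include_salt_mnc = TRUE) {
  if (is.null(edges)) {
    div <- c("rare_bacterial", "abundant_bacterial",
             "rare_fungal", "abundant_fungal")
    edges <- rbind(
      data.frame(from = "salt", to = div, stringsAsFactors = FALSE),
      data.frame(from = div, to = "mnc", stringsAsFactors = FALSE))
    if (include_salt_mnc)
      edges <- rbind(edges, data.frame(from = "salt", to = "mnc"))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate path", call. = FALSE)
  vars <- unique(c(edges$from, edges$to))
  # topological order; fails on cycles
  order <- character(0)
  pool <- vars
  while (length(pool)) {
    free <- pool[vapply(pool, function(v)
      !any(edges$to == v & edges$from %in% pool), logical(1))]
    if (!length(free)) stop("path specification is cyclic", call. = FALSE)
    order <- c(order, free)
    pool <- setdiff(pool, free)
  }
  exo <- setdiff(vars, edges$to)
  if (!length(exo)) stop("need at least one exogenous variable",
                         call. = FALSE)
  structure(list(edges = edges, variables = order, exogenous = exo,
                 endogenous = setdiff(order, exo)),
            class = "rc_path_spec")
}

#' Fit a recursive path model
#'
#' Classic recursive path analysis on observed variables: each
#' endogenous variable is regressed on its parents after z-scoring all
#' variables, giving standardized path coefficients with t-based
#' two-sided p-values.  Global fit compares the sample correlation
#' matrix S with the model-implied covariance assembled from the path
#' coefficients and residual variances:
#' F_ML = ln|Sigma| - ln|S| + tr(S Sigma^-1) - k, chi-square =
#' (n - 1) F_ML, df = k(k+1)/2 - (paths + residual variances + exogenous
#' (co)variances), RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1))) (0 for
#' a saturated model).
#'
#' @param data data frame of observed per-sample variables (complete
#'   cases).
#' @param spec a [path_model_spec()].
#' @return An object of class `rc_path_fit`: list with `paths` (data
#'   frame `from`, `to`, `coefficient`, `se`, `p_value`), `r_squared`
#'   per endogenous variable, `chi_square`, `df`, `chi_df_ratio`,
#'   `rmsea`, `n`.
#' @export
fit_path_model <- function(data, spec = path_model_spec()) {
  stopifnot(inherits(spec, "rc_path_spec"))
  miss <- setdiff(spec$variables, names(data))
  if (length(miss))
    stop("variables missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(data)[spec$variables]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  k <- length(spec$variables)
  n_par <- nrow(spec$edges) + length(spec$endogenous) +
    length(spec$exogenous) * (length(spec$exogenous) + 1) / 2
  dof <- k * (k + 1) / 2 - n_par
  if (dof < 0) stop("model has more parameters than moments",
                    call. = FALSE)
  if (n <= n_par) stop("fewer samples than parameters", call. = FALSE)
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(names(sds)[sds == 0], collapse = ", "), call. = FALSE)
  z <- as.data.frame(scale(df))

  paths <- spec$edges
  paths$coefficient <- NA_real_
  paths$se <- NA_real_
  paths$p_value <- NA_real_
  r2 <- stats::setNames(numeric(length(spec$endogenous)),
                        spec$endogenous)
  B <- matrix(0, k, k, dimnames = list(spec$variables, spec$variables))
  psi <- stats::setNames(rep(NA_real_, k), spec$variables)
  for (v in spec$endogenous) {
    parents <- spec$edges$from[spec$edges$to == v]
    fit <- stats::lm(stats::reformulate(parents, response = v), data = z)
    if (anyNA(stats::coef(fit)))
      stop("singular design in equation for ", v, call. = FALSE)
    sm <- summary(fit)
    co <- sm$coefficients
    for (p in parents) {
      i <- which(paths$from == p & paths$to == v)
      paths$coefficient[i] <- co[p, 1]
      paths$se[i] <- co[p, 2]
      paths$p_value[i] <- co[p, 4]
    }
    r2[v] <- sm$r.squared
    B[v, parents] <- co[parents, 1]
    psi[v] <- sum(stats::residuals(fit)^2) / (n - 1)
  }

  S <- stats::cov(z)
  omega <- matrix(0, k, k, dimnames = dimnames(S))
  exo <- spec$exogenous
  omega[exo, exo] <- S[exo, exo, drop = FALSE]
  for (v in spec$endogenous) omega[v, v] <- psi[v]
  iB <- solve(diag(k) - B)
  sigma <- iB %*% omega %*% t(iB)
  chi2 <- tryCatch({
    f_ml <- as.numeric(determinant(sigma)$modulus -
                         determinant(S)$modulus +
                         sum(diag(S %*% solve(sigma))) - k)
    max((n - 1) * f_ml, 0)
  }, error = function(e) {
    # a saturated recursive model reproduces S exactly; with residual
    # variances of zero the discrepancy is 0/0 and resolves to 0
    if (dof == 0) 0 else stop(e)
  })
  if (dof == 0 && !is.finite(chi2)) chi2 <- 0
  rmsea <- if (dof == 0) 0 else
    sqrt(max(chi2 - dof, 0) / (dof * (n - 1)))
  structure(list(paths = paths, r_squared = r2, chi_square = chi2,
                 df = dof,
                 chi_df_ratio = if (dof > 0) chi2 / dof else NA_real_,
                 rmsea = rmsea, n = n, spec = spec,
                 implied = sigma, sample_cov = S),
            class = "rc_path_fit")
}

#' @export
print.rc_path_fit <- function(x, ...) {
  cat(sprintf("recursive path model: n = %d, chi2 = %.3f, df = %d, ",
              x$n, x$chi_square, x$df))
  cat(sprintf("chi2/df = %s, RMSEA = %.3f\n",
              ifelse(is.na(x$chi_df_ratio), "NA",
                     sprintf("%.3f", x$chi_df_ratio)), x$rmsea))
  pp <- x$paths
  pp$coefficient <- round(pp$coefficient, 3)
  pp$p_value <- signif(pp$p_value, 3)
  print(pp[c("from", "to", "coefficient", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Random-forest permutation importance
#'
#' Regression forest (bootstrap resampling, `ceiling(p/3)` candidate
#' predictors per split) with out-of-bag permutation importance,
#' expressed as the percent increase in out-of-bag MSE when a
#' predictor's values are permuted, relative to the mean OOB MSE.
#'
#' @param predictors data frame of predictor variables (>= 2 columns).
#' @param response numeric response (e.g. rare-taxa Shannon index).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return An object of class `rc_importance`: list with `importance`
#'   (data frame `predictor`, `inc_mse_pct`, sorted descending),
#'   `r_squared`, `n_trees`, `seed`.
#' @export
rf_importance <- function(predictors, response, n_trees = 500, seed = 1L) {
  x <- as.data.frame(predictors)
  if (ncol(x) < 2) stop("need at least 2 predictors", call. = FALSE)
  if (nrow(x) < 10) stop("need at least 10 samples", call. = FALSE)
  if (length(response) != nrow(x))
    stop("response length must match predictors", call. = FALSE)
  if (stats::sd(response) == 0) {
    warning("constant response: importances are zero", call. = FALSE)
    imp <- data.frame(predictor = names(x), inc_mse_pct = 0)
    return(structure(list(importance = imp, r_squared = NA_real_,
                          n_trees = n_trees, seed = seed),
                     class = "rc_importance"))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x, y = response, ntree = n_trees,
    mtry = ceiling(ncol(x) / 3), importance = TRUE)
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  pct <- 100 * raw / mean(fit$mse)
  imp <- data.frame(predictor = names(pct), inc_mse_pct = unname(pct),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$inc_mse_pct), , drop = FALSE]
  rownames(imp) <- NULL
  structure(list(importance = imp,
                 r_squared = fit$rsq[n_trees],
                 n_trees = n_trees, seed = seed),
            class = "rc_importance")
}

#' @export
print.rc_importance <- function(x, ...) {
  cat(sprintf("random-forest permutation importance (%d trees, R2 = %.3f)\n",
              x$n_trees, x$r_squared))
  print(transform(x$importance, inc_mse_pct = round(inc_mse_pct, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Assemble the per-sample driver modelling table
#'
#' Joins, on sample id, the salinity, the four sub-community Shannon
#' indices (rare/abundant x bacteria/fungi), the MNC and the seven MNC
#' nutrient variables into one modelling table (12 columns, sample ids
#' as row names), complete-case filtered.
#'
#' @param bacteria,fungi [otu_table()]s.
#' @param nutrients a [nutrient_table()].
#' @param rare_max,abundant_min classification thresholds
#'   (see [classify_taxa()]).
#' @return Data frame with columns `salt`, `rare_bacterial`,
#'   `abundant_bacterial`, `rare_fungal`, `abundant_fungal`, `mnc` and
#'   the seven [mnc_vars()].
#' @export
assemble_driver_table <- function(bacteria, fungi, nutrients,
                                  rare_max = 1e-5, abundant_min = 5e-4) {
  nutrients <- nutrient_table(nutrients)
  ids <- Reduce(intersect, list(sample_ids(bacteria), sample_ids(fungi),
                                nutrients$sample_id))
  if (length(ids) < 3)
    stop("fewer than 3 shared samples across inputs", call. = FALSE)
  shannon_by_class <- function(t, which) {
    t <- subset_otu_table(t, samples = ids)
    cls <- classify_taxa(t, rare_max, abundant_min)
    ad <- alpha_diversity(subset_by_class(t, cls, which))
    stats::setNames(ad$shannon, ad$sample_id)[ids]
  }
  nut <- nutrients[match(ids, nutrients$sample_id), , drop = FALSE]
  mnc <- compute_mnc(nut)
  out <- data.frame(
    salt = nut$salt,
    rare_bacterial = shannon_by_class(bacteria, "rare"),
    abundant_bacterial = shannon_by_class(bacteria, "abundant"),
    rare_fungal = shannon_by_class(fungi, "rare"),
    abundant_fungal = shannon_by_class(fungi, "abundant"),
    mnc = unname(mnc$mnc[ids]),
    row.names = ids)
  for (v in mnc_vars()) out[[v]] <- nut[[v]]
  cc <- stats::complete.cases(out)
  if (sum(cc) < nrow(out))
    message(nrow(out) - sum(cc), " incomplete case(s) dropped")
  out[cc, , drop = FALSE]
}
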