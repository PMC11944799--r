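# Seeded synthetic data with the statistical structure the analysis
# assumes: 41 samples in four crop groups, crop-stratified truncated-
# normal nutrients, lognormal species-abundance distributions populating
# both the >0.05% and <0.001% relative-abundance tails, and a planted
# causal chain salinity -> rare bacterial diversity -> multi-nutrient
# status (negative) with a positive rare fungal route.

#' Default per-crop nutrient means and SDs
#'
#' Crop-stratified mean and SD for each of the thirteen nutrient
#' variables, matching the study design the generator emulates.
#'
#' @return Named list (per crop) of variable x (mean, sd) matrices.
#' @export
default_nutrient_params <- function() {
  v <- nutrient_vars()
  mk <- function(means, sds) {
    m <- cbind(mean = means, sd = sds)
    rownames(m) <- v
    m
  }
  list(
    soybean = mk(c(8.64, 0.76, 1.37, 11.51, 1.29, 45.6, 14.90, 116,
                   0.05, 2.75, 18.2, 1.46, 5.76),
                 c(0.08, 0.13, 0.02, 1.17, 0.09, 13.87, 4.18, 5.93,
                   0.01, 0.34, 2.10, 0.43, 0.36)),
    cotton  = mk(c(8.65, 1.69, 1.43, 16.29, 2.53, 79.7, 28.13, 158,
                   0.08, 2.51, 14.7, 1.64, 6.87),
                 c(0.07, 0.26, 0.03, 1.25, 0.10, 13.97, 8.23, 14.70,
                   0.01, 0.24, 1.58, 0.62, 0.73)),
    sorghum = mk(c(8.53, 1.34, 1.46, 18.70, 2.75, 99.0, 22.54, 135,
                   0.10, 2.96, 24.3, 6.23, 8.69),
                 c(0.02, 0.19, 0.03, 1.73, 0.24, 9.98, 5.87, 19.26,
                   0.01, 0.33, 3.20, 2.20, 1.22)),
    maize   = mk(c(8.59, 0.74, 1.39, 14.07, 2.56, 78.5, 17.13, 149,
                   0.08, 3.13, 15.6, 2.14, 7.66),
                 c(0.05, 0.12, 0.03, 1.58, 0.10, 9.87, 2.83, 16.25,
                   0.01, 0.37, 1.28, 0.46, 0.72)))
}

# Dominant phyla used for synthetic taxonomy strings, most to least
# abundant.
synth_phyla <- function(kingdom) {
  if (kingdom == "bacteria")
    c("Proteobacteria", "Acidobacteriota", "Actinobacteria", "Chloroflexi",
      "Planctomycetes", "Gemmatimonadota", "Bacteroidota", "Firmicutes",
      "Myxococcota", "Methylomirabilota", "unclassified")
  else
    c("Ascomycota", "Mortierellomycota", "Basidiomycota",
      "unclassified_k_Fungi", "Chytridiomycota", "Glomeromycota",
      "Rozellomycota", "Zoopagomycota", "Blastocladiomycota",
      "Kickxellomycota", "unclassified")
}

#' Synthetic dataset configuration
#'
#' @param n_samples named integer vector of samples per crop (defaults to
#'   the study design: soybean 10, cotton 11, sorghum 5, maize 15).
#' @param n_otus named integer vector `c(bacteria = , fungi = )`.
#' @param sad_sigma lognormal shape of the species-abundance
#'   distribution (log scale SD; default 2).
#' @param sample_sigma per-sample lognormal perturbation of the
#'   abundance profile (default 0.3).
#' @param depth sequencing depth per sample (default 30000).
#' @param crop_nutrient_params per-crop mean/SD matrices
#'   ([default_nutrient_params()]).
#' @param path_effects planted standardized effects for the coupled
#'   generator: `salt_to_rare_bacterial`, `rare_bacterial_to_mnc`,
#'   `rare_fungal_to_mnc` (defaults +0.40, -0.31, +0.47).
#' @param coupling low-level constants of the coupled generator: per
#'   kingdom, the fraction of OTUs assigned to the rare pool
#'   (`rare_pool_fraction`), the total relative-abundance mass of that
#'   pool (`rare_mass`), the baseline number of active rare OTUs per
#'   sample (`k0`) and the log-richness gain per diversity SD
#'   (`k_gain`); plus `nutrient_loading`, the correlation of each MNC
#'   nutrient with the latent nutrient-status factor.
#' @param seed integer seed.
#' @return A validated list of class `rc_synth_config`.
#' @export
synth_config <- function(n_samples = c(soybean = 10, cotton = 11,
                                       sorghum = 5, maize = 15),
                         n_otus = c(bacteria = 5000, fungi = 800),
                         sad_sigma = 2, sample_sigma = 0.3, depth = 30000,
                         crop_nutrient_params = default_nutrient_params(),
                         path_effects = c(salt_to_rare_bacterial = 0.40,
                                          rare_bacterial_to_mnc = -0.31,
                                          rare_fungal_to_mnc = 0.47),
                         coupling = NULL, seed = 1L) {
  if (any(n_samples < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (!(sad_sigma > 0)) stop("sad_sigma must be > 0", call. = FALSE)
  if (sample_sigma < 0) stop("sample_sigma must be >= 0", call. = FALSE)
  if (!(depth > 0)) stop("depth must be > 0", call. = FALSE)
  if (any(n_otus < 10)) stop("n_otus must be >= 10", call. = FALSE)
  if (any(abs(path_effects) >= 1))
    stop("path effects must lie in (-1, 1)", call. = FALSE)
  for (cr in names(n_samples)) {
    pm <- crop_nutrient_params[[cr]]
    if (is.null(pm)) stop("no nutrient parameters for crop ", cr,
                          call. = FALSE)
    if (any(pm[, "sd"] < 0)) stop("negative SD for crop ", cr,
                                  call. = FALSE)
  }
  default_coupling <- list(
    bacteria = list(rare_pool_fraction = 0.8, rare_mass = 0.03,
                    k0 = 150, k_gain = 0.3),
    fungi = list(rare_pool_fraction = 0.75, rare_mass = 0.005,
                 k0 = 40, k_gain = 0.3),
    nutrient_loading = 0.9)
  if (!is.null(coupling))
    default_coupling[names(coupling)] <- coupling
  structure(list(n_samples = n_samples, n_otus = n_otus,
                 sad_sigma = sad_sigma, sample_sigma = sample_sigma,
                 depth = depth, crop_nutrient_params = crop_nutrient_params,
                 path_effects = path_effects,
                 coupling = default_coupling, seed = as.integer(seed)),
            class = "rc_synth_config")
}

synth_sample_ids <- function(cfg) {
  crops <- rep(names(cfg$n_samples), cfg$n_samples)
  ids <- unlist(lapply(names(cfg$n_samples), function(cr)
    sprintf("%s_%02d", cr, seq_len(cfg$n_samples[[cr]]))),
    use.names = FALSE)
  stats::setNames(crops, ids)
}

# draw a truncated-at-zero normal by redrawing negatives
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) {
    bad <- x < 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic nutrient table
#'
#' Per crop, each variable is drawn from a normal with the configured
#' mean and SD, truncated at zero (negatives are redrawn), so per-crop
#' sample means converge to the configured means.
#'
#' @param cfg a [synth_config()].
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return A [nutrient_table()].
#' @export
generate_nutrients <- function(cfg = synth_config(), seed = NULL) {
  stopifnot(inherits(cfg, "rc_synth_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  crops <- synth_sample_ids(cfg)
  out <- data.frame(sample_id = names(crops), crop = unname(crops),
                    stringsAsFactors = FALSE)
  for (v in nutrient_vars()) out[[v]] <- NA_real_
  for (cr in names(cfg$n_samples)) {
    pm <- cfg$crop_nutrient_params[[cr]]
    rows <- which(out$crop == cr)
    for (v in nutrient_vars())
      out[[v]][rows] <- rtruncnorm0(length(rows), pm[v, "mean"],
                                    pm[v, "sd"])
  }
  nutrient_table(out)
}

#' Generate a synthetic OTU table
#'
#' Per-sample counts are a multinomial draw of the configured depth from
#' a lognormal(0, sad_sigma^2) abundance profile with an independent
#' per-sample lognormal perturbation (sample_sigma).  Under the default
#' parameters the mean relative-abundance spectrum populates both the
#' abundant (>0.05%) and rare (<0.001%) tails.  Taxonomy strings carry
#' the dominant phyla of the emulated communities.
#'
#' @param cfg a [synth_config()].
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param seed optional seed override.
#' @return An [otu_table()].
#' @export
generate_otu_table <- function(cfg = synth_config(),
                               kingdom = c("bacteria", "fungi"),
                               seed = NULL) {
  stopifnot(inherits(cfg, "rc_synth_config"))
  kingdom <- match.arg(kingdom)
  set.seed(if (is.null(seed))
    derive_seed(cfg$seed, if (kingdom == "bacteria") 1L else 2L) else seed)
  n <- cfg$n_otus[[kingdom]]
  crops <- synth_sample_ids(cfg)
  l <- stats::rnorm(n, 0, cfg$sad_sigma)
  counts <- matrix(0L, length(crops), n,
                   dimnames = list(names(crops),
                                   sprintf("%s_OTU%04d",
                                           substr(kingdom, 1, 1), 1:n)))
  for (s in seq_along(crops)) {
    a <- exp(l + stats::rnorm(n, 0, cfg$sample_sigma))
    counts[s, ] <- stats::rmultinom(1, cfg$depth, a / sum(a))
  }
  otu_table(counts, crop = crops,
            taxonomy = synth_taxonomy(n, kingdom))
}

synth_taxonomy <- function(n, kingdom) {
  phyla <- synth_phyla(kingdom)
  w <- c(28, 19, 15, 10, 8, 6, 5, 4, 2, 1, 2)
  ph <- sample(phyla, n, replace = TRUE, prob = w / sum(w))
  root <- if (kingdom == "bacteria") "d__Bacteria" else "k__Fungi"
  ifelse(ph == "unclassified", "unclassified",
         paste0(root, ";p__", ph))
}

# Count table with a planted rare-tail richness gradient: the designated
# rare pool holds a fixed total mass; per sample, that mass is spread
# uniformly over k(s) = k0 * exp(k_gain * eta_s) pool members chosen at
# random, so the rare sub-community Shannon index is (up to sampling
# noise) ln k(s), i.e. linear in the latent diversity score eta.
synth_kingdom_counts <- function(cfg, kingdom, eta) {
  n <- cfg$n_otus[[kingdom]]
  cp <- cfg$coupling[[kingdom]]
  n_rare <- round(cp$rare_pool_fraction * n)
  n_core <- n - n_rare
  # keep the rare pool's expected per-OTU share safely inside the
  # <0.001% tail, and the active-subset baseline inside the pool
  m_rare <- min(cp$rare_mass, 0.8 * 1e-5 * n_rare)
  k0 <- min(cp$k0, max(5L, floor(n_rare / 3)))
  crops <- synth_sample_ids(cfg)
  ns <- length(crops)

  l_core <- stats::rnorm(n_core, 0, cfg$sad_sigma)
  ids <- sprintf("%s_OTU%04d", substr(kingdom, 1, 1), seq_len(n))
  counts <- matrix(0L, ns, n, dimnames = list(names(crops), ids))
  core_idx <- seq_len(n_core)
  rare_idx <- n_core + seq_len(n_rare)
  k <- pmin(pmax(round(k0 * exp(cp$k_gain * eta)), 5L), n_rare)
  for (s in seq_len(ns)) {
    a_core <- exp(l_core + stats::rnorm(n_core, 0, cfg$sample_sigma))
    p <- numeric(n)
    p[core_idx] <- (1 - m_rare) * a_core / sum(a_core)
    active <- sample.int(n_rare, k[s])
    p[rare_idx[active]] <- m_rare / k[s]
    counts[s, ] <- stats::rmultinom(1, cfg$depth, p)
  }
  otu_table(counts, crop = crops, taxonomy = synth_taxonomy(n, kingdom))
}

rare_shannon_z <- function(t) {
  cls <- classify_taxa(t)
  ad <- alpha_diversity(subset_by_class(t, cls, "rare"))
  as.numeric(scale(ad$shannon))
}

#' Generate a coupled (causally structured) synthetic dataset
#'
#' Emulates the planted causal structure: realized soil salinity drives
#' the latent rare bacterial diversity score (standardized effect
#' `salt_to_rare_bacterial`); the rare-tail richness of the bacterial and
#' fungal tables encodes the latent scores; and the seven MNC nutrients
#' load on a latent nutrient-status factor built from the *realized*
#' (count-derived) standardized rare Shannon values with effects
#' `rare_bacterial_to_mnc` and `rare_fungal_to_mnc`.  Non-MNC variables
#' (pH, salt, BD, SWC, NH4-N, AN) keep their crop-stratified
#' distributions; the MNC nutrients are drawn around pooled means so the
#' planted effects are not confounded with crop identity.
#'
#' @param cfg a [synth_config()].
#' @param seed optional seed override.
#' @return List with `bacteria` and `fungi` ([otu_table()]s),
#'   `nutrients` ([nutrient_table()]) and `truth` (planted standardized
#'   path coefficients and the latent scores).
#' @export
generate_coupled_dataset <- function(cfg = synth_config(), seed = NULL) {
  stopifnot(inherits(cfg, "rc_synth_config"))
  base_seed <- if (is.null(seed)) cfg$seed else seed
  nut <- generate_nutrients(cfg, seed = derive_seed(base_seed, 11L))

  set.seed(derive_seed(base_seed, 12L))
  z_salt <- as.numeric(scale(nut$salt))
  b_sb <- cfg$path_effects[["salt_to_rare_bacterial"]]
  eta_b <- b_sb * z_salt + sqrt(1 - b_sb^2) * stats::rnorm(nrow(nut))
  eta_f <- stats::rnorm(nrow(nut))

  set.seed(derive_seed(base_seed, 13L))
  bact <- synth_kingdom_counts(cfg, "bacteria", eta_b)
  set.seed(derive_seed(base_seed, 14L))
  fung <- synth_kingdom_counts(cfg, "fungi", eta_f)

  z_b <- rare_shannon_z(bact)
  z_f <- rare_shannon_z(fung)

  b_bm <- cfg$path_effects[["rare_bacterial_to_mnc"]]
  b_fm <- cfg$path_effects[["rare_fungal_to_mnc"]]
  resid_var <- 1 - b_bm^2 - b_fm^2
  if (resid_var <= 0)
    stop("rare-to-MNC effects imply residual variance <= 0", call. = FALSE)
  set.seed(derive_seed(base_seed, 15L))
  eta_n <- b_bm * z_b + b_fm * z_f +
    sqrt(resid_var) * stats::rnorm(nrow(nut))

  # pooled (abundance-weighted) means and mean SDs across crops
  rho <- cfg$coupling$nutrient_loading
  w <- cfg$n_samples / sum(cfg$n_samples)
  for (v in mnc_vars()) {
    mu <- sum(vapply(names(w), function(cr)
      cfg$crop_nutrient_params[[cr]][v, "mean"], numeric(1)) * w)
    sg <- mean(vapply(names(w), function(cr)
      cfg$crop_nutrient_params[[cr]][v, "sd"], numeric(1)))
    val <- mu + sg * (rho * eta_n +
                        sqrt(1 - rho^2) * stats::rnorm(nrow(nut)))
    nut[[v]] <- pmax(val, 0)
  }
  truth <- list(
    path = c(salt_to_rare_bacterial = b_sb,
             salt_to_abundant_bacterial = 0,
             salt_to_rare_fungal = 0,
             salt_to_abundant_fungal = 0,
             rare_bacterial_to_mnc = b_bm,
             rare_fungal_to_mnc = b_fm,
             abundant_bacterial_to_mnc = 0,
             abundant_fungal_to_mnc = 0,
             salt_to_mnc = 0),
    eta_bacterial = eta_b, eta_fungal = eta_f, eta_nutrient = eta_n)
  list(bacteria = bact, fungi = fung, nutrients = nutrient_table(nut),
       truth = truth)
}
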