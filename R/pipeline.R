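# One-call orchestration of the full analysis: ingest or synthesise data,
# partition taxa, diversity statistics, MNC, per-crop co-occurrence
# networks, correlation screens, path model and random-forest importance.
# Every stage draws from a seed derived from the single run seed by a
# fixed counter, and the JSON report is byte-identical for identical
# config + seed.

#' Pipeline run configuration
#'
#' Either a synthetic block (`synth`) or paths to an OTU TSV pair and a
#' nutrient CSV.
#'
#' @param synth a [synth_config()] (used when file paths are `NULL`).
#' @param otu_bacteria,otu_fungi,nutrients input file paths.
#' @param rare_max,abundant_min taxa classification thresholds.
#' @param keep_fraction,r_min,alpha network thresholds
#'   (see [network_config()]).
#' @param n_perm permutations for PERMANOVA/Mantel (default 999).
#' @param seed global run seed.
#' @param out_dir output directory (created if needed).
#' @return A validated list of class `rc_run_config`.
#' @export
run_config <- function(synth = synth_config(), otu_bacteria = NULL,
                       otu_fungi = NULL, nutrients = NULL,
                       rare_max = 1e-5, abundant_min = 5e-4,
                       keep_fraction = 0.8, r_min = 0.60, alpha = 0.05,
                       n_perm = 999, seed = 1L, out_dir = tempfile("rcrun")) {
  files <- c(otu_bacteria, otu_fungi, nutrients)
  if (length(files) && length(files) != 3)
    stop("provide all three input paths or none", call. = FALSE)
  if (length(files) && !all(file.exists(files)))
    stop("input file(s) not found: ",
         paste(files[!file.exists(files)], collapse = ", "), call. = FALSE)
  if (!length(files)) stopifnot(inherits(synth, "rc_synth_config"))
  if (!(rare_max > 0 && rare_max < abundant_min && abundant_min < 1))
    stop("need 0 < rare_max < abundant_min < 1", call. = FALSE)
  net_cfg <- network_config(keep_fraction, r_min, alpha)  # validates
  if (!(n_perm >= 1)) stop("n_perm must be >= 1", call. = FALSE)
  structure(list(synth = synth, otu_bacteria = otu_bacteria,
                 otu_fungi = otu_fungi, nutrients = nutrients,
                 rare_max = rare_max, abundant_min = abundant_min,
                 network = net_cfg, n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "rc_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synth` map
#' is passed to [synth_config()].
#'
#' @param path YAML file.
#' @return A `rc_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    sc <- y$synth
    if (!is.null(sc$n_samples)) sc$n_samples <- unlist(sc$n_samples)
    if (!is.null(sc$n_otus)) sc$n_otus <- unlist(sc$n_otus)
    if (!is.null(sc$path_effects)) sc$path_effects <- unlist(sc$path_effects)
    y$synth <- do.call(synth_config, sc)
  }
  do.call(run_config, y)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/synthesis, taxa partition, diversity (alpha,
#' Bray-Curtis, NMDS, Kruskal-Wallis, PERMANOVA, Mantel, Duncan), MNC,
#' per-crop co-occurrence networks with topology, correlation screens,
#' path model and random-forest importance.  A stage error marks the
#' stage failed and skips everything downstream; the report is always
#' written.  Identical config + seed produce a byte-identical
#' `report.json`.
#'
#' @param cfg a [run_config()].
#' @return The run report (list), invisibly; artifacts and `report.json`
#'   are written under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "rc_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed,
                 thresholds = list(rare_max = cfg$rare_max,
                                   abundant_min = cfg$abundant_min,
                                   keep_fraction = cfg$network$keep_fraction,
                                   r_min = cfg$network$r_min,
                                   alpha = cfg$network$alpha,
                                   n_perm = cfg$n_perm),
                 stages = list())
  env <- new.env(parent = emptyenv())
  failed <- FALSE
  stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(list(status = "ok", out = fun()),
                    error = function(e)
                      list(status = "failed", message = conditionMessage(e)))
    if (res$status == "failed") {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     message = res$message)
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res$out)
    }
    invisible(NULL)
  }

  stage("data", function() {
    if (is.null(cfg$otu_bacteria)) {
      synth <- cfg$synth
      synth$seed <- derive_seed(cfg$seed, 1L)
      ds <- generate_coupled_dataset(synth)
      env$bacteria <- ds$bacteria; env$fungi <- ds$fungi
      env$nutrients <- ds$nutrients
      write_otu_table(ds$bacteria, file.path(cfg$out_dir,
                                             "otu_bacteria.tsv"))
      write_otu_table(ds$fungi, file.path(cfg$out_dir, "otu_fungi.tsv"))
      write_nutrient_table(ds$nutrients,
                           file.path(cfg$out_dir, "nutrients.csv"))
      write_json_file(as.list(ds$truth$path),
                      file.path(cfg$out_dir, "truth.json"))
      list(source = "synthetic")
    } else {
      nut <- read_nutrient_table(cfg$nutrients)
      crop <- stats::setNames(nut$crop, nut$sample_id)
      env$bacteria <- read_otu_table(cfg$otu_bacteria, crop = crop)
      env$fungi <- read_otu_table(cfg$otu_fungi, crop = crop)
      env$nutrients <- nut
      list(source = "files")
    }
  })

  stage("partition", function() {
    out <- list()
    for (kg in c("bacteria", "fungi")) {
      t <- env[[kg]]
      cls <- classify_taxa(t, cfg$rare_max, cfg$abundant_min)
      env[[paste0("class_", kg)]] <- cls
      write_tsv(data.frame(otu_id = names(cls$class),
                           mean_rel_abund = unname(cls$mean_rel_abund),
                           class = as.character(cls$class)),
                file.path(cfg$out_dir, paste0("labels_", kg, ".tsv")))
      out[[kg]] <- as.list(stats::setNames(as.integer(cls$counts),
                                           names(cls$counts)))
    }
    ov <- otu_overlap(env$bacteria)
    write_json_file(as.list(ov$intersections),
                    file.path(cfg$out_dir, "overlap_bacteria.json"))
    out
  })

  stage("diversity", function() {
    out <- list()
    for (kg in c("bacteria", "fungi")) {
      t <- env[[kg]]
      ad <- alpha_diversity(t)
      write_tsv(ad, file.path(cfg$out_dir, paste0("alpha_", kg, ".tsv")))
      bc <- bray_curtis(t)
      write_tsv(data.frame(sample_id = rownames(bc), bc,
                           check.names = FALSE),
                file.path(cfg$out_dir, paste0("bray_curtis_", kg, ".tsv")))
      nm <- run_nmds(bc, seed = derive_seed(cfg$seed, 21L))
      write_tsv(data.frame(sample_id = rownames(nm$points), nm$points,
                           check.names = FALSE),
                file.path(cfg$out_dir, paste0("nmds_", kg, ".tsv")))
      pmv <- permanova(bc, t$crop, n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, 22L))
      kw <- kruskal_wallis(ad$shannon, ad$crop)
      nm_env <- scale(as.data.frame(env$nutrients)[nutrient_vars()])
      rownames(nm_env) <- env$nutrients$sample_id
      env_d <- as.matrix(stats::dist(nm_env))[rownames(bc), rownames(bc)]
      mt <- mantel_test(bc, env_d, n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, 23L))
      out[[kg]] <- list(nmds_stress = nm$stress,
                        permanova_F = pmv$statistic,
                        permanova_R2 = pmv$effect,
                        permanova_p = pmv$p_value,
                        kruskal_H = kw$statistic, kruskal_p = kw$p_value,
                        mantel_r = mt$statistic, mantel_p = mt$p_value)
    }
    write_json_file(out, file.path(cfg$out_dir, "tests.json"))
    out
  })

  stage("mnc", function() {
    mnc <- compute_mnc(env$nutrients)
    env$mnc <- mnc
    duncan <- anova_duncan(mnc$mnc, mnc$crop)
    write_tsv(data.frame(sample_id = names(mnc$mnc), crop = mnc$crop,
                         mnc = unname(mnc$mnc), mnc$normalized,
                         check.names = FALSE),
              file.path(cfg$out_dir, "mnc.tsv"))
    write_tsv(duncan, file.path(cfg$out_dir, "mnc_duncan.tsv"))
    list(mean_mnc = mean(mnc$mnc),
         crop_means = as.list(tapply(mnc$mnc, mnc$crop, mean)))
  })

  stage("networks", function() {
    out <- list()
    topo_all <- list()
    for (kg in c("bacteria", "fungi")) {
      for (cr in sort(unique(env[[kg]]$crop))) {
        sub <- subset_otu_table(env[[kg]],
                                samples = names(env[[kg]]$crop)[
                                  env[[kg]]$crop == cr])
        sub <- prevalence_filter_top(sub, cfg$network$keep_fraction)
        sp <- suppressWarnings(spearman_matrix(sub))
        net <- suppressWarnings(build_network(sp$r, sp$p, cfg$network))
        key <- paste(kg, cr, sep = "_")
        if (igraph::ecount(net$graph) > 0) {
          mods <- detect_modules(net, seed = derive_seed(cfg$seed, 31L))
          igraph::V(net$graph)$module <-
            as.integer(mods$membership[igraph::V(net$graph)$name])
          write_network(net, file.path(cfg$out_dir,
                                       paste0("network_", key, ".graphml")))
          topo <- topology_summary(net, seed = derive_seed(cfg$seed, 31L))
          topo_all[[key]] <- unclass(topo)
          out[[key]] <- list(nodes = topo$node_num, edges = topo$edge_num)
        } else {
          topo_all[[key]] <- list(node_num = 0, edge_num = 0)
          out[[key]] <- list(nodes = 0, edges = 0)
        }
        rm(sp); gc(FALSE)
      }
    }
    write_json_file(topo_all, file.path(cfg$out_dir, "topology.json"))
    out
  })

  stage("correlations", function() {
    nut <- as.data.frame(env$nutrients)[mnc_vars()]
    out <- list()
    for (kg in c("bacteria", "fungi")) {
      t <- env[[kg]]
      cls <- env[[paste0("class_", kg)]]
      res <- list()
      for (wh in c("rare", "abundant")) {
        ad <- alpha_diversity(subset_by_class(t, cls, wh))
        sc <- correlation_screen(
          data.frame(shannon = ad$shannon), nut, method = "spearman")
        sc$class <- wh
        res[[wh]] <- sc
      }
      scr <- do.call(rbind, res)
      write_tsv(scr, file.path(cfg$out_dir,
                               paste0("correlations_", kg, ".tsv")))
      out[[kg]] <- nrow(scr)
    }
    out
  })

  stage("drivers", function() {
    tab <- assemble_driver_table(env$bacteria, env$fungi, env$nutrients,
                                 cfg$rare_max, cfg$abundant_min)
    write_tsv(data.frame(sample_id = rownames(tab), tab,
                         check.names = FALSE),
              file.path(cfg$out_dir, "driver_table.tsv"))
    fit <- fit_path_model(tab, path_model_spec())
    write_json_file(list(paths = fit$paths,
                         chi_square = fit$chi_square, df = fit$df,
                         chi_df_ratio = fit$chi_df_ratio,
                         rmsea = fit$rmsea),
                    file.path(cfg$out_dir, "path_fit.json"))
    imp <- list()
    for (kg in c("bacteria", "fungi")) {
      resp <- tab[[paste0("rare_",
                          if (kg == "bacteria") "bacterial" else "fungal")]]
      ri <- rf_importance(tab[mnc_vars()], resp,
                          seed = derive_seed(cfg$seed, 41L))
      write_json_file(ri$importance,
                      file.path(cfg$out_dir,
                                paste0("importance_", kg, ".json")))
      imp[[kg]] <- ri$importance$predictor[1]
    }
    pc <- fit$paths
    key_paths <- list(
      salt_to_rare_bacterial = pc$coefficient[
        pc$from == "salt" & pc$to == "rare_bacterial"],
      rare_bacterial_to_mnc = pc$coefficient[
        pc$from == "rare_bacterial" & pc$to == "mnc"],
      rare_fungal_to_mnc = pc$coefficient[
        pc$from == "rare_fungal" & pc$to == "mnc"])
    list(paths = key_paths, rmsea = fit$rmsea,
         chi_df_ratio = fit$chi_df_ratio, rf_top = imp)
  })

  report$status <- if (failed) "failed" else "ok"
  write_json_file(report, file.path(cfg$out_dir, "report.json"))
  report$report_hash <- unname(tools::md5sum(
    file.path(cfg$out_dir, "report.json")))
  invisible(report)
}
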