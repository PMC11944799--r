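# rarecycle

Soil microbial communities split into a few **abundant** taxa and a long
tail of **rare** ones, and field studies increasingly find that the rare
tail — not the dominant organisms — tracks how well a soil cycles its
nutrients.  `rarecycle` is an R package for that style of analysis: it
links the diversity of rare and abundant soil bacteria and fungi
(OTU-level 16S/ITS community tables) to a **soil multi-nutrient cycling
index (MNC)** across crop types, with co-occurrence network topology,
permutation statistics and a causal path model, and it ships a seeded
synthetic-data generator so the entire pipeline is testable without any
external download.

## What it computes

* **Taxa partitioning** — OTUs are classed by mean relative abundance
  across samples: *abundant* above 0.05 %, *rare* below 0.001 %,
  *intermediate* between (both thresholds configurable).
* **Multi-nutrient cycling index** — each of seven nutrient variables
  (SOC, TN, TP, TK, Olsen-P, Avail-K, NO3-N) is min–max normalised over
  all samples, `N = (X − X_min)/(X_max − X_min)`, and the per-sample MNC
  is the mean of the seven normalised values.
* **Diversity statistics** — richness, Shannon (nats) and Pielou
  evenness; Bray–Curtis dissimilarity; NMDS ordination (Kruskal
  stress-1); PERMANOVA and Mantel tests with 999 permutations;
  Kruskal–Wallis; one-way ANOVA with Duncan's multiple range test and
  connected-letter reports.
* **Co-occurrence networks** — per crop, the top 80 % of OTUs by mean
  relative abundance are correlated (Spearman); edges keep |r| > 0.60
  and p < 0.05; topology summaries cover seventeen descriptors
  (degree, density, path length, Louvain modularity, clustering,
  transitivity, assortativity, centralization, edge-sign fractions, …)
  plus **robustness**: the mean relative size of the largest connected
  component after randomly removing half the nodes.
* **Drivers** — a recursive path model (standardized coefficients,
  chi-square/df, RMSEA) linking salinity, the four sub-community Shannon
  indices and the MNC, and random-forest permutation importance
  (% increase in out-of-bag MSE) of the nutrient variables for rare-taxa
  diversity.

## Worked example

```r
library(rarecycle)

cfg <- synth_config(seed = 1)          # 41 samples, 4 crop groups
ds  <- generate_coupled_dataset(cfg)   # bacteria + fungi + nutrients

classify_taxa(ds$bacteria)
#> taxa classification (rare < 1e-05, abundant > 0.0005):
#>         rare intermediate     abundant
#>         2888         1847          265

tab <- assemble_driver_table(ds$bacteria, ds$fungi, ds$nutrients)
fit_path_model(tab)
#> recursive path model: n = 41, chi2 = 3.642, df = 6, chi2/df = 0.607, RMSEA = 0.000
#>                from                 to coefficient p_value
#>                salt     rare_bacterial       0.439 0.00412
#>      rare_bacterial                mnc      -0.255 0.11900
#>         rare_fungal                mnc       0.491 0.00245
#>                ...                 ...         ...     ...
```

The classification shows a realistic rare biosphere (about 58 % of OTUs
below the 0.001 % threshold).  The path model recovers, at study scale,
the generator's planted structure: salinity raises rare bacterial
diversity (0.439), rare bacterial diversity lowers the MNC (−0.255) and
rare fungal diversity raises it (0.491); chi2/df < 2 and RMSEA ≈ 0
indicate an acceptable fit.  Crop means of the MNC on crop-stratified
synthetic nutrients reproduce the expected ordering (sorghum highest):

```r
mnc <- compute_mnc(generate_nutrients(cfg))
round(tapply(mnc$mnc, mnc$crop, mean), 2)
#>  cotton   maize sorghum soybean
#>    0.40    0.40    0.66    0.25
```

The whole analysis can also be driven by one call —
`run_pipeline(run_config(seed = 42, out_dir = "out"))` — which writes
alpha/beta diversity tables, NMDS coordinates, MNC, per-crop GraphML
networks with topology JSON, correlation screens, the path-model fit and
RF importances, plus a deterministic `report.json` (identical
config + seed gives a byte-identical report).  `run_config()` also
accepts three input files (bacterial and fungal OTU TSV, nutrient CSV)
instead of the synthetic block, and `read_run_config()` loads the same
settings from YAML.

## Package layout

* `R/` — io (`read_otu_table`, `read_nutrient_table`, `write_network`),
  synthetic data (`synth_config`, `generate_coupled_dataset`),
  partitioning (`classify_taxa`, `prevalence_filter_top`,
  `otu_overlap`), diversity (`alpha_diversity`, `permanova`,
  `anova_duncan`, …), MNC (`compute_mnc`, `availability_ratios`),
  networks (`spearman_matrix`, `build_network`, `topology_summary`,
  `network_robustness`), drivers (`fit_path_model`, `rf_importance`)
  and the pipeline (`run_pipeline`).
* `vignettes/rarecycle-methods.Rmd` — the methods vignette: model
  definitions, generator design, numerical choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles.
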