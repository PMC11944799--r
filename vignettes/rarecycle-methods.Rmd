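---
title: "Methods: rare taxa, co-occurrence networks and soil multi-nutrient cycling"
author: "rarecycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare taxa, co-occurrence networks and soil multi-nutrient cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific conventions the package fixes:
what each statistic means, which knobs matter, how the synthetic-data
generator is built, and where genuinely open design choices were
resolved.

## The analysis in one paragraph

A soil community table (samples × OTUs, with taxonomy and a crop label
per sample) and a paired nutrient table (thirteen physicochemical
variables) enter the pipeline.  OTUs are partitioned into rare and
abundant sub-communities by relative-abundance thresholds; each
sub-community's alpha diversity (Shannon) and the whole community's
beta diversity (Bray–Curtis, NMDS, PERMANOVA) are computed; the seven
nutrient-cycling variables are folded into a per-sample multi-nutrient
cycling index (MNC); per-crop co-occurrence networks summarise
community organisation; and a recursive path model plus random-forest
importance rank the drivers that connect salinity, rare-taxa diversity
and the MNC.

## Taxa partitioning

An OTU is **abundant** when its *mean relative abundance across all
samples* exceeds `abundant_min` (default 5e-4, i.e. 0.05 %), **rare**
when it is below `rare_max` (default 1e-5, i.e. 0.001 %), and
**intermediate** otherwise.  Both comparisons are strict, making the
three classes exhaustive and exclusive.  Averaging across samples
(rather than thresholding per sample) is the convention of the
rare-biosphere literature; both thresholds are arguments of
`classify_taxa()`.  Intermediate OTUs belong to neither sub-community:
only the two tails are defined, and silently assigning the middle to
either side would blur exactly the contrast under study.

The network pre-filter `prevalence_filter_top()` keeps the top 80 % *of
OTU identities* ranked by mean relative abundance (ties broken by OTU
id, so the filter is deterministic).  The alternative reading — 80 % of
cumulative abundance — would retain far fewer OTUs; the count-based
reading is used because the filter is described as acting on OTUs, and
the fraction is an argument.

## Alpha and beta diversity

Shannon diversity is computed on relative abundances in **nats**
(natural log, with 0·ln 0 = 0).  Pielou evenness is
`shannon / ln(richness)` (0 for a single-OTU sample), which ties the
three reported indices together: an evenness of 0.86 follows from a
Shannon of 7.06 at a richness of 3704 only in natural-log units, and
that identity is one of the package's acceptance checks.  Counts are
used as-is (relative-abundance conversion only, no rarefaction): the
emulated study reports none, and subsampling would add a stochastic
layer the permutation tests would then have to marginalise over.

Bray–Curtis dissimilarity, NMDS (Kruskal stress-1, `monoMDS` engine,
20 random starts, k = 2 — two axes, matching the two-dimensional
ordinations the design emulates), PERMANOVA (single factor, free
permutation of labels, 999 permutations, p = (1 + #{F* ≥ F})/(n+1))
and the Mantel test are delegated to **vegan**, the standard tool for
exactly these computations; the package pins the conventions and seeds
and verifies the pseudo-F against a direct implementation of the
distance-based sum-of-squares partition in its test suite.  Type-I
calibration of both permutation tests (rejection rate at α = 0.05
within [0.035, 0.065] over 1000 null simulations) is part of the
acceptance suite.

Duncan's multiple range test is implemented in the package (no CRAN
dependency provides it among the package's imports): one-way ANOVA
gives the MSE; the least significant range for a span of *p* ordered
means uses the studentized range quantile at Duncan's protection level
`(1 − α)^(p−1)` with the harmonic mean group size for unbalanced
designs; a range contained in a non-significant wider range is itself
non-significant; maximal runs of mutually non-significant means become
connected letters sorted by descending mean.

Correlation screens expose both Pearson and Spearman (both appear in
this literature for the same question; neither is privileged).
Spearman p-values use the exact null distribution for n ≤ 10 without
ties and the t approximation otherwise — the smallest crop group has
five samples, where the approximation is unreliable.

## The multi-nutrient cycling index

Each variable is min–max normalised over **all samples jointly** (not
per crop):

$$N = \frac{X - X_{min}}{X_{max} - X_{min}}, \qquad
  \mathrm{MNC} = \frac{1}{n}\sum_{i=1}^{n} N_i$$

with the seven defaults SOC, TN, TP, TK, Olsen-P, Avail-K and NO3-N.
The index is therefore invariant to the units of every input, monotone
in each variable, and bounded in [0, 1] with both endpoints attained.
A constant variable is a hard error: its normalisation is undefined and
silently dropping it would change *n*, i.e. the definition of the
index.  Availability ratios (AN:TN, Olsen-P:TP, Avail-K:TK) are
reported in percent, with mg kg⁻¹ numerators divided by 1000 against
g kg⁻¹ totals.

## Co-occurrence networks

Within each crop's sample subset, the prevalence-filtered OTU profiles
are Spearman-correlated (average-rank ties).  Two-sided p-values use
the t approximation `t = r sqrt((n−2)/(1−r²))`, the usual screening
convention for all-against-all OTU matrices (an exact permutation null
for millions of pairs is not practical; the approximation is documented
rather than hidden).  An edge requires `|r| > 0.60` **and** `p < 0.05`,
both strict, with no multiple-testing correction by default (a raw
p-threshold is the fidelity-first choice; Benjamini–Hochberg is one
flag away).  Edge weight is |r|; the sign is stored separately.
Isolated OTUs are not part of the network: node counts refer to
connected nodes only, which is the only reading consistent with
published node counts being far below the OTU counts that enter the
correlation step.

The topology summary reports: average degree 2E/N; average weighted
degree (mean node strength on |r|); diameter and average path length
(unweighted, on the largest connected component); density
2E/(N(N−1)); Louvain modularity and community count on |r| weights
(resolution 1, seeded — the common default of network visualisation
tools); mean local clustering (degree < 2 contributes 0); global
transitivity; degree assortativity; Freeman degree centralization
`Σ(d_max − d_i) / ((N−1)(N−2))`; the mean over nodes of the mean degree
of their neighbours ("average neighbors" — this exceeds the average
degree in the tabulated networks this package emulates, which is the
friendship-paradox direction and motivates the mean-neighbour-degree
reading of that ambiguous label); edge-sign fractions; and robustness.

**Robustness** is defined here as the mean relative size of the largest
connected component after removing `floor(0.5·N)` nodes uniformly at
random, averaged over 100 seeded replicates.  The index is named but
not defined in the literature this package emulates; this is the
dominant convention in microbial network studies, and both the removal
fraction and replicate count are arguments.  On a complete graph the
value is exactly the retained fraction, which the tests exploit.

Every metric is validated against an independent brute-force
implementation (adjacency-matrix loops, Floyd–Warshall paths, explicit
modularity sum) on 100 random graphs in the acceptance suite.

## The path model

The driver layer is classic recursive path analysis on observed
variables: salinity points at the four sub-community Shannon indices,
and those four plus salinity point at the MNC (the direct
salinity→MNC edge is included by default — with the edge present the
model makes no unwarranted df claim about it; `include_salt_mnc =
FALSE` drops it).  All variables are z-scored, each endogenous variable
is fit by least squares on its parents (for a recursive
observed-variable model these are the maximum-likelihood standardized
coefficients), and global fit compares the sample correlation matrix S
with the implied covariance `Σ = (I−B)⁻¹ Ω (I−B)⁻ᵀ`:

* `F_ML = ln|Σ| − ln|S| + tr(S Σ⁻¹) − k`
* `χ² = (n−1) F_ML`, `df = k(k+1)/2 − (paths + residual variances +
  exogenous (co)variances)`
* `RMSEA = sqrt(max(χ² − df, 0) / (df (n−1)))`, 0 when df = 0.

A saturated model reproduces S exactly (χ² = 0, RMSEA = 0), a
single-predictor equation's coefficient equals the Pearson correlation,
and the fit statistics are invariant to affine rescaling of any
variable — all asserted in the tests.  Latent variables, modification
indices and bootstrap intervals are out of scope.

Random-forest importance uses a 500-tree regression forest
(`ceiling(p/3)` candidate predictors per split) and reports the
out-of-bag permutation importance as a percentage of the mean OOB MSE —
the %IncMSE convention of ecology figures.  One model is fit per
kingdom with the rare-taxa Shannon index as response.

## The synthetic-data generator

The generator emulates the study design so every downstream stage is
testable offline: 41 samples in four crop groups (soybean 10, cotton
11, sorghum 5, maize 15), crop-stratified nutrients, lognormal
species-abundance distributions, and a planted causal chain.

* **Nutrients** are truncated-at-zero normals per crop, with default
  means and SDs taken from the emulated study's soil table (only means
  and SDs are reported, so the simplest distribution matching those
  summaries is used; negatives are redrawn).  Units follow the
  nutrient-table convention (salt in permille, mg kg⁻¹ for available
  nutrient fractions, g kg⁻¹ for totals).
* **Community tables** (`generate_otu_table`) draw per-sample counts as
  a multinomial of the configured depth (default 30 000) from a
  lognormal abundance profile (`sad_sigma`, default 2 — no dispersion
  information is available for the emulated communities, so this is a
  documented free knob) perturbed per sample by an independent
  lognormal factor (`sample_sigma`, default 0.3).  At the default
  scale this populates both classification tails (roughly 55–60 % of
  OTUs rare, a few hundred abundant).  Default OTU counts (5000
  bacteria, 800 fungi) are deliberately below the tens of thousands in
  real surveys to keep every test in seconds.
* **The coupled dataset** (`generate_coupled_dataset`) plants the
  standardized effects salinity → rare bacterial diversity (+0.40),
  rare bacterial diversity → nutrient status (−0.31) and rare fungal
  diversity → nutrient status (+0.47).  The mechanism: a latent
  diversity score η is drawn per sample (η for bacteria is 0.40·z(salt)
  plus matched noise); each kingdom's designated rare pool (80 % of
  bacterial, 75 % of fungal OTUs, holding a fixed total mass of
  relative abundance, capped so the pool's mean per-OTU share stays
  inside the rare tail) is spread uniformly over k(s) = k₀·exp(0.3 η)
  active members per sample, so the realized rare-tail Shannon index is
  ln k(s) up to sampling noise — *linear in η*, which is what makes the
  planted standardized effects recoverable.  The seven MNC nutrients
  then load (loading 0.9) on a latent nutrient-status factor built from
  the *realized*, count-derived standardized rare Shannon values, so
  the diversity→MNC effects suffer no measurement attenuation.  The
  MNC nutrients of the coupled dataset are drawn around pooled (not
  crop-stratified) means: crop-structured nutrient means combined with
  crop-structured salinity would confound the planted coefficients
  with crop identity, which is exactly what a recovery test must not
  have.  Non-MNC variables (pH, salt, BD, SWC, NH4-N, AN) keep their
  crop structure.  The generative direction — nutrients shifted by
  realized diversity — matches the arrows of the path model, keeping
  recovery well-posed.

What the generator does **not** emulate: sequencing error and chimeras,
compositional artifacts, phylogenetic or spatial autocorrelation,
crop-driven community composition shifts (the coupled tables differ
between crops only through salinity), and dispersion structure beyond
the lognormal.  Passing tests therefore demonstrate that the *methods*
are implemented to their definitions and that planted linear structure
is recovered — not that real soil data will show these effects.

## Determinism and problem sizes

All randomness flows from integer seeds; per-stage seeds are derived
from the run seed by a fixed counter scheme (`derive_seed`), so adding
a stage never changes earlier stages' draws, and two runs with the same
config and seed produce byte-identical JSON reports.  The test suite
uses: 100 random graphs (≤ 15 nodes) for the topology oracles; 1000
null simulations with 199 permutations each for the type-I calibration
of PERMANOVA and Mantel (199 keeps the achievable p-value grid aligned
with α = 0.05 while the full analyses default to 999); 20 seeds at
n = 500 for path-coefficient recovery, asserting the 20-seed mean of
each planted coefficient within ±0.1 and its bias below 0.05 (a single
seed carries multinomial noise of about ±0.05 on a coefficient, so the
mean is the stable recovery target); and 50 seeded forests for the
planted-predictor ranking.

## Known limitations

* Robustness and the "average neighbors" metric implement documented
  interpretations of ambiguous labels; published values of those two
  metrics are not reproducible without the original data *and* the
  original definitions, so the package asserts only the metrics whose
  definitions are fixed (degree, density identities are checked against
  published node/edge counts exactly).
* The cohesion index sometimes mentioned alongside robustness has no
  published definition or values in the emulated analysis and is
  deliberately absent.
* Spearman p-values in the all-against-all network screen use the t
  approximation even at n = 5; with the strict |r| > 0.6 gate this
  admits slightly more small-n edges than an exact null would.
* The path model is observed-variable and recursive; feedback loops or
  latent constructs need a full SEM engine.
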