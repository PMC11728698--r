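---
title: "Evaluating taxonomic profilers in a common feature space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating taxonomic profilers in a common feature space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxeval)
```

## The problem

Shotgun-metagenomic taxonomic profilers (Kraken+Bracken, MetaPhlAn,
mOTUs, ...) each report relative abundances against their own reference
catalogue — their *native feature space*. Because the catalogues carve
the same microbial diversity into different species-level units, their
outputs cannot be compared to one another, or to a simulation's ground
truth, until everything is expressed in one *common feature space*
(e.g. GTDB or UHGG species). `taxeval` implements that evaluation
pipeline: projection into the common space with explicit loss
accounting, a per-sample metric suite, community-structure comparison,
and systematic confused-species detection — plus a synthetic-data module
so the entire pipeline is exercised end to end without any external
downloads.

## Projection and loss accounting

A `feature_mapping` is a weighted many-to-many relation from native to
common feature ids; for each native feature its weights sum to 1.
`project()` applies four rules, in the fixed order *split → sum → drop →
renormalize*:

1. native features hitting the same common feature are **summed**;
2. a native feature with several targets is **split** proportionally to
   its mapping weights;
3. unmapped native features (and, under `species_only = TRUE`, features
   whose target carries a rank label other than `"species"`) are
   **omitted**, accruing to the per-sample *lost abundance* and *lost
   features* accounts;
4. columns are **renormalized** to unit sum.

Only drop-before-renormalize is semantically forced (renormalization is
defined on the table obtained *after* conversion); the split/sum order
is immaterial because both are linear. Mass is conserved by
construction: pre-normalization projected mass plus lost abundance
equals the input column sum to 1e-9, a property tested on random
instances. A sample that loses *all* its abundance is left all-zero and
flagged rather than renormalized (renormalizing a zero column is
undefined; flagging keeps the bookkeeping honest). A native feature
whose targets are only partially filtered contributes its filtered mass
to lost abundance but is not counted in lost features, which counts
fully dropped features with nonzero abundance in the specific sample.

## The per-sample metric suite

For a reference profile $u$ and an estimate $v$ over a shared feature
index (features present in only one table are imputed as exact zeros),
`evaluate_sample_set()` computes per sample:

* **Richness / Shannon error** — estimated minus reference richness
  (count of nonzero features) and Shannon entropy
  $H = -\sum_{x_i>0} x_i \ln x_i$ in nats.
* **Sensitivity and precision** — $TP/(TP+FN)$ and $TP/(TP+FP)$ on the
  presence/absence support sets. "Present" means abundance strictly
  greater than 0; no detection threshold is applied, because projection
  emits exact zeros. Zero denominators yield `NA`, which is excluded
  from medians with the exclusion count reported.
* **FPRA / FNRA** — summed estimated abundance over false positives and
  summed reference abundance over false negatives;
  $TPRA = 1 - FPRA$.
* **Bray–Curtis** — $d_{BC} = \sum_i |u_i - v_i| \,/\, \sum_i (u_i + v_i)$.
* **Weighted UniFrac** —
  $d_{WUF} = \sum_i b_i |u_i - v_i| \,/\, \sum_i b_i (u_i + v_i)$, the
  sums running over the branches of a rooted phylogeny with branch
  lengths $b_i$, where $u_i$ is the total abundance of leaves descending
  from branch $i$. On a star tree with equal branch lengths this reduces
  exactly to Bray–Curtis — a useful cross-check that the test suite
  exercises. Features carrying abundance but absent from the tree are
  dropped with renormalization and a warning (an error in
  `strict_tree` mode); the choice is a package convention.
* **Aitchison** — Euclidean distance between clr-transformed
  compositions after multiplicative zero replacement: each zero becomes
  $\delta$ and nonzero entries are rescaled by $1 - z\delta$ ($z$ =
  number of zeros), preserving the unit sum. The default
  $\delta = 1/D^2$ ($D$ = number of features) follows the convention of
  the compositional-analysis literature; it is exposed as a parameter
  because the distance (unlike its rank ordering) is sensitive to it.

Medians across samples use the midpoint convention for even counts.

## Community structure

`pairwise_distances()` builds the sample-by-sample distance matrix for
either table; `jensen_shannon()` compares two such matrices by
normalizing their upper triangles to unit sum (a package convention —
distance matrices are not probability distributions, so some such
closure is needed) and computing
$JSD(p, q) = \tfrac12 D(p\|m) + \tfrac12 D(q\|m)$, $m = (p+q)/2$, in
natural log, bounded by $\ln 2$. A compatibility flag
(`kl_denominator = "printed"`) computes the symmetrized plain KL
divergence instead, which is unbounded and not recommended; the mixture
form is the Jensen–Shannon construction and is the default.

## Confused species pairs

A profiler that cannot separate two close relatives reports the
abundance of the species it misses under the other's name. For a
candidate (FN, FP) pair only *eligible* samples are informative: the FN
feature must be present in the reference and absent from the estimate
while the FP feature is absent from the reference and present in the
estimate. `find_confused_pairs()` reports pairs with at least 25
eligible samples (default) whose Pearson correlation between the FN's
reference abundance and the FP's estimated abundance strictly exceeds
0.5 (0.9 for a high-confidence list). Series with fewer than three
distinct values are skipped as degenerate. Both directions of a pair
are reported as distinct records when both qualify. The fast
enumeration (per-sample FN/FP incidence matrices and a cross-product of
indicator matrices) is verified against a brute-force all-pairs oracle.

## What the simulator emulates — and what it does not

`sim_config()` / `generate_scenario()` produce profile-level synthetic
data: log-normal long-tailed communities with per-sample richness drawn
around a target (default 343 samples, a 1000-species universe, richness
200 — giving Shannon diversities around 4.8–5 nats, the order seen in
real gut-microbiome profiles of that richness), plus a profiler-error
model applied in the fixed order *confusion → dropout → FP injection →
multiplicative noise*, then renormalization. Dropout probability falls
linearly in log-abundance from `dropout_rate_at_min` at the sample's
rarest feature to 0 at its most abundant, mimicking the
detection-limit behaviour of real profilers; injected false positives
are drawn below the sample's median truth abundance, since spurious
calls are typically low-abundance.

The simulator operates on profiles, not reads: it does not model
sequencing error, genome similarity, coverage, or catalogue content, so
passing tests demonstrate the correctness of the *evaluation machinery*
and the qualitative error-mode arithmetic, not any statement about how
real profilers perform on real reads. Abundances are i.i.d. across
features within a sample (no ecological covariance), and the mapping
generator produces structural (unmapped / split / shared-target) cases
without taxonomy.

Every generator is a pure function of its seed: truth draws use
`seed`, profiler error draws `seed + 1`, mapping assignment `seed + 2`
and the phylogeny `seed + 3`, so the components can be varied
independently.

## Numerical and design choices

* Tables are features-in-rows, samples-in-columns; abundances are
  proportions in $[0,1]$ (a `percent` flag rescales percentage
  exports). Writers emit 12 significant digits, so files round-trip to
  1e-12 and are byte-stable.
* Shannon entropy is in nats throughout.
* Reference tables are treated as already common-space: projecting them
  through an identity mapping is the identity and loses nothing.
* Ranking of tools is strictly per metric after transforming medians to
  $[0,1]$ similarities ($1 - |u-v|/(u+v)$ for richness/Shannon,
  $1 - d$ for the two bounded distances, $TPRA = 1 - FPRA$, sensitivity
  and precision untouched); no composite score is computed. The
  Aitchison distance is excluded from the similarity map because
  $1 - d$ would not lie in $[0,1]$ for an unbounded distance.
* Ties in medians and rankings use midpoints and shared (min) ranks.

## Problem sizes used in the test suite

The bundled checks run the headline scenario (343 samples, 1000
features) for the perfect-profiler and contrasting-profiler analyses,
20 seeded replicates of 250 samples × 200 features for confusion-pair
recovery, 3 error levels × 20 seeds at 60 samples × 300 features for
the monotone-degradation property, and 200 random trees of up to 12
leaves for the brute-force metric oracles. These sizes were chosen so
the full suite exercises every pipeline stage at realistic scale while
remaining quick to run on a laptop.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_samples = 50, n_features = 400, richness_mean = 120,
                  seed = 1, fp_injection_rate = 40,
                  dropout_rate_at_min = 0.3, noise_sigma = 0.1,
                  unmapped_fraction = 0.05, split_fraction = 0.1)
sc <- generate_scenario(cfg)

proj <- project(sc$truth, sc$mapping)
loss_summary(list(simulated_tool = proj))

ev <- evaluate_sample_set(sc$truth, sc$est, tree = sc$tree)
print(ev)

find_confused_pairs(sc$truth, sc$est, min_samples = 10)
```

## Known limitations

Real benchmarking adds layers this package deliberately treats as
inputs: building the native-to-common mapping (a read-classification
problem in its own right), read-level simulation, and the profilers
themselves. Eukaryotes and viruses, genus-level aggregation,
unweighted UniFrac and rarefaction are out of scope. The Jensen–Shannon
comparison depends on the upper-triangle closure convention; comparing
its absolute values across studies that normalize differently is not
meaningful.
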