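# taxeval

Benchmarking shotgun-metagenomic taxonomic profilers is confounded by
the fact that every profiler reports abundances against its own
reference catalogue. `taxeval` is an R toolkit for evaluating profilers
against a ground truth once all tables are expressed in a **common
feature space** (such as GTDB or UHGG species). It is aimed at
bioinformaticians running profiler benchmarks and at method developers
who need a self-contained, fully testable evaluation pipeline.

The package provides:

* **Projection** (`project()`): converts an abundance table from a
  native to a common feature space through a weighted feature mapping —
  summing natives that merge, splitting natives proportionally across
  several targets, omitting unmapped (or non-species-rank) features
  with per-sample *lost abundance* / *lost features* accounting, and
  renormalizing. Mass is conserved to 1e-9 by construction.
* **Per-sample metrics** (`evaluate_sample_set()`): richness and
  Shannon-diversity error (nats); sensitivity `TP/(TP+FN)` and
  precision `TP/(TP+FP)` on presence/absence; false-positive and
  false-negative relative abundance (FPRA, FNRA); Bray–Curtis
  `Σ|u−v| / Σ(u+v)`; weighted UniFrac
  `Σ bᵢ|uᵢ−vᵢ| / Σ bᵢ(uᵢ+vᵢ)` over the branches of a rooted
  phylogeny; Aitchison distance (clr with multiplicative zero
  replacement, default δ = 1/D²).
* **Community structure** (`pairwise_distances()`,
  `jensen_shannon()`): Jensen–Shannon divergence between the truth's
  and a profiler's pairwise distance matrices, bounded by ln 2.
* **Confused-pair detection** (`find_confused_pairs()`): species pairs
  where a profiler systematically reports a missed taxon (FN) under a
  close relative's name (FP), found by Pearson correlation across the
  samples where the pair is a clean FN/FP split (defaults: ≥ 25
  eligible samples, r > 0.5).
* **A synthetic-data module** (`sim_config()`, `generate_scenario()`):
  seeded log-normal communities plus a parameterized profiler error
  model (sibling confusion, abundance-dependent dropout, false-positive
  injection, multiplicative noise), feature mappings and random
  phylogenies — so the entire pipeline runs and is tested with no
  external data.

## A worked example

Simulate a flawed profiler on a 50-sample community, project the truth
through a cross-catalogue mapping, and evaluate:

```r
library(taxeval)

cfg <- sim_config(n_samples = 50, n_features = 400, richness_mean = 120,
                  seed = 1, fp_injection_rate = 40,
                  dropout_rate_at_min = 0.3, noise_sigma = 0.1,
                  unmapped_fraction = 0.05, split_fraction = 0.1)
sc <- generate_scenario(cfg)

proj <- project(sc$truth, sc$mapping)
loss_summary(list(simulated_tool = proj))
#>             tool median_lost_abundance median_lost_features
#> 1 simulated_tool            0.04633924                    6

evaluate_sample_set(sc$truth, sc$est, tree = sc$tree)
#> Profiler evaluation over 50 sample(s)
#> Medians across samples:
#>   richness_diff  23
#>   shannon_diff   0.10758
#>   bray_curtis    0.13155
#>   unifrac        0.053771
#>   aitchison      44.236
#>   sensitivity    0.85543
#>   precision      0.71841
#>   fpra           0.10301
#>   fnra           0.082065
```

Reading the output: this simulated profiler over-calls richness by a
median of 23 species, injected false positives carry 10% of the
estimated abundance (FPRA 0.103), and dropout of rare species costs 14%
sensitivity — while the community remains close to the truth in the
phylogeny-aware UniFrac distance (0.054), as expected when errors fall
on low-abundance taxa.

A thin command-line dispatcher over the same functions is installed at
`system.file("cli", "taxeval.R", package = "taxeval")` with subcommands
`project`, `evaluate`, `community`, `confusions`, `simulate` and
`summarize`.

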