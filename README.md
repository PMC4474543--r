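# oncotopo

Comparative profiling of cancer gene sets — tumor suppressor genes (TSGs),
oncogenes (OCGs), drug-target genes, essential genes, and the interactome
complement ("other") — by somatic mutation frequency and protein–protein
interaction (PPI) network topology, for computational cancer biologists who
want the whole analysis as a tested, scriptable pipeline rather than a chain
of one-off scripts.

## What it computes

**Mutation burden.** For gene *g* and sample stratum *S* (a tumor type, or
all samples),

```
f(g, S) = 100 · |{ s ∈ S : s has ≥ 1 somatic mutation in g }| / |S|
```

with denominators taken from an explicit sample manifest (mutation-free
samples count). Each gene set is summarized by the distribution of its
members' frequencies; sets are contrasted with the two-sample
Kolmogorov–Smirnov statistic `D = sup_x |F̂₁(x) − F̂₂(x)|` and its
asymptotic two-sided p-value.

**Network topology.** Per node: degree, unnormalized Brandes betweenness,
local clustering coefficient `2·e(N(v)) / k(k−1)`, and mean breadth-first
shortest-path distance to reachable nodes; per set: distributions, means and
pairwise K-S tests. Plus the distance profile of every set around the
drug-target set (proportion of members at each shortest-path distance
0–8, with overlap members at 0) and each set's direct-interaction fraction
(members with ≥ 1 target neighbor).

**TSG–OCG subnetwork.** The Klein–Ravi `2 ln k` spider-merge approximation
of the node-weighted Steiner tree connecting the two terminal sets (unit
linker weights, lexicographic tie-breaks, redundant-linker pruning), then
the *induced* subgraph on the chosen nodes with edges categorized A–A, B–B,
A–B or linker-involving, composition percents, and Pearson correlation of
subnetwork degree with mutation frequency.

**Synthetic data.** A seeded generator (scale-free networks, hub-biased
planted sets with weight `degree^α`, Bernoulli mutations with per-set rates
and tumor-type multipliers) emulating the statistical structure the analysis
assumes, so everything above is testable offline.

## Worked example

```r
library(oncotopo)

study   <- synthetic_study(synthetic_spec(seed = 1))   # network + sets + mutations
catalog <- build_catalog(study$network, study$sets)
profile <- set_frequency_profile(study$table, catalog)
glance(profile)
#>   mean_TSG mean_OCG mean_Target mean_Essential mean_Other
#> 1     5.18    0.988       0.447          0.191      0.206
```

The planted 5% / 1% / 0.5% / 0.2% rate ladder is recovered in the set means.
Topology shows the hub bias (α = 2 for TSGs, 1 for OCGs) as the familiar
degree / path-length ladder:

```r
topology_profile(study$network, catalog)
#> <topology_profile> 1000 nodes, 5 sets
#>   set       degree betweenness clustering mean_spd
#> 1 TSG        23.8       11647.     0.0190     3.03
#> 2 OCG         7.88       1718.     0.0199     3.38
#> 3 Target      5.53        805.     0.0419     3.41
#> 4 Essential   5.91        905.     0.0367     3.41
#> 5 Other       4.50        492.     0.0307     3.48
```

and the Steiner module ties the two views together:

```r
inst   <- steiner_instance(study$network, union(study$sets$TSG, study$sets$OCG))
subnet <- induced_subnetwork(study$network, klein_ravi(inst),
                             study$sets$TSG, study$sets$OCG)
subnet <- attach_mutation_frequency(subnet, profile)
subnet
#> <steiner_subnetwork> 112 nodes (linker: 12, terminal-A: 50, terminal-B: 50),
#>                      213 edges (111 in tree)
edge_composition(subnet)
#> <composition_summary> 213 edges; among-terminal 170 (79.8%)
#>   A-A                 88 ( 41.3%)
#>   B-B                 11 (  5.2%)
#>   A-B                 71 ( 33.3%)
#>   linker-involving    43 ( 20.2%)
degree_frequency_correlation(subnet)
#> <pearson_result> r = 0.317, p = 0.000654 (n = 112, t)
```

100 terminals need only 12 linkers, ~80% of edges run among the terminals
themselves, and mutation frequency correlates positively with subnetwork
degree — the qualitative signature this analysis is built to detect.

The same analysis runs end to end from a YAML config
(`inst/extdata/synthetic_config.yaml` ships a 300-node fixture):

```r
cfg <- pipeline_config(system.file("extdata", "synthetic_config.yaml", package = "oncotopo"))
cfg$outdir <- "my_run"
run_pipeline(cfg)   # writes TSV/JSON tables + report.json with checksums
```

Real data drop in through `read_interactions()` (edge-list TSV, PSI-MI TAB,
SIF), `read_gene_list()` (GMT, one-per-line) and `read_mutation_table()`
(MAF-like TSV with a configurable column mapping and optional sample
manifest).

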