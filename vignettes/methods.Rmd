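---
title: "Methods: compound over-representation analysis and drug-gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound over-representation analysis and drug-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`oranet` treats drug repurposing as an over-representation problem. A
chemical–gene association database (the kind CTD, STITCH, Connectivity Map
or DrugBank exports produce) assigns each compound an annotation set of
gene symbols. Given a curated disease gene list, a compound whose
annotation set overlaps the list more than random sampling would predict is
a candidate for repurposing.

The statistic is the hypergeometric upper tail. Let $N$ be the background
universe (by default, every gene with at least one annotation in the loaded
table), $M$ the compound's annotated genes, $n$ the query-list size after
intersecting with the universe, and $k$ the observed overlap. Then

$$P = \Pr(X \ge k) = 1 - \sum_{i=0}^{k-1}
      \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

the probability that a uniform draw of $n$ genes without replacement
contains at least $k$ annotated ones. P-values are adjusted across all
tested annotation sets by the Benjamini–Hochberg step-up rule
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, clamped at 1), and compounds
with $q < \alpha$ (default 0.05) are retained, ranked by ascending $p$ with
ties broken by descending $k$, then chemical id, then source.

**Assumptions.** The null model is exchangeable sampling of query genes
from the universe: it ignores annotation bias (well-studied drugs and genes
carry more annotations), gene–gene dependence, and the direction of
regulation. These are properties of the data source, not of the statistic;
the synthetic-data generator reproduces exactly this null, which is why its
calibration results certify the implementation rather than any real
database.

## What counts as one test

Published hit tables list one row per compound *and source* (the same
chemical can appear under CTD and under STITCH with different statistics,
and redundant entries are consolidated afterwards). `enrich()` therefore
tests each (chemical, source) annotation set separately by default, with
the two Connectivity Map directions pooled into a single CMAP set
(`split_cmap_direction = TRUE` keeps them apart, since sources do not
document how direction should enter a disease-gene query);
`by_source = FALSE` pools everything per chemical, which is also the view
the network stage uses. The BH denominator $m$ is the number of sets
actually tested — by default those with $k \ge 1$, configurable via
`min_hits = 0` to test every set. Both conventions are exposed because
upstream enrichment services do not publish theirs.

## Consolidation policy

When one chemical survives under several sources, `consolidate_duplicates()`
keeps a single record. The default keeps the most significant record
(`min_p`); the alternative `max_p` keeps the least significant one, which
is the literal reading of retaining "the compound with the higher P value"
in the workflow this package reimplements. Retaining the weaker record is
unusual — it understates evidence — so the conservative-looking literal rule
is available but not the default. q-values are not recomputed after
consolidation (they answer "significant among all tested sets");
`requalify = TRUE` re-runs BH on the survivors for users who want
per-report FDR.

# Numerical choices

* **Log-space tail.** Top hits in compound ORA reach $p \sim 10^{-70}$,
  far below where `1 - lower_tail` underflows. `hyper_tail_p()` sums the
  upper tail directly with log-gamma binomials combined by log-sum-exp and
  clamps to $[0, 1]$. Against exhaustive enumeration it is accurate to
  better than $10^{-10}$ relative error over the full small-$N$ sweep, and
  it agrees with `stats::phyper(lower.tail = FALSE)` (used only as a
  cross-check) across random configurations.
* **BH arithmetic.** The step-up factor is computed as `p * (m/j)` so that
  the top rank ($j = m$) leaves `p` bit-identical, keeping the invariant
  $q \ge p$ exact in floating point.
* **Tie-breaking** in ranks is deterministic (p, then $-k$, then chemical
  id, then source), so reruns are byte-identical.
* **Degenerate inputs.** $k = 0$ returns $p = 1$ exactly; a query disjoint
  from the universe is an error ("no testable genes"); an edgeless network
  is a warning, not an error, but its density is undefined and errors when
  requested.

# Networks

`build_network()` connects each selected drug to its annotated genes inside
the target gene set (sources pooled; provenance kept as an edge attribute).
Metrics follow the conventions of common network tools:

* **Density** is $E/(D \cdot G)$ — realized over maximum possible
  drug–gene edges. This is the only formula consistent with the published
  full-network figures (886 interactions between 27 drugs and 174 genes
  giving 0.19) and with most of the published per-subtype rows; the one or
  two rows it cannot reproduce appear to use a unipartite formula
  inconsistently, and the package deliberately computes the bipartite form
  everywhere.
* **Mean drug degree** is $E/D$ (for the full network, $886/27 = 32.8$,
  i.e. each drug touches about 19% of the 174 genes).
* **Closeness** is computed per connected component as
  $(|C|-1)/\sum d(v,\cdot)$ with unit edge weights (0 for isolated
  nodes), and **edge betweenness** counts all-pairs shortest paths with
  fractional tie weighting. Shortest-path machinery comes from igraph;
  both metrics are validated against brute-force path enumeration in the
  test suite.
* **Low-degree gene filter.** Genes with fewer than `min_degree = 3` drug
  connections are dropped in a single pass (one pass is idempotent:
  removing a gene cannot reduce another gene's degree). Drugs left
  isolated are retained by default so drug counts continue to reflect the
  selection, with `prune_isolated_drugs = TRUE` available.
* **Export, not layout.** GraphML carries bipartite side, degree,
  closeness, subtype and edge betweenness so any viewer can size and shade
  nodes; force-directed layout is presentation, not analysis, and is left
  to the viewer.

The pathway stage reuses the identical code path with pathways in place of
chemicals (asserted bit-identical in tests). Pathway selection defaults to
"top K by q-value" (K = 6 in the published workflow): the eye-catching
significance cutoffs printed alongside such selections are the observed
K-th q-value of a particular database snapshot, not portable constants.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes:

* a universe of `universe_size` synthetic genes (`G000001`…; synthetic ids
  avoid accidental biological reading) and `n_compounds` compounds;
* per-compound annotation sizes $M$ log-uniform between
  `annotation_size_range` bounds;
* null compounds draw their sets uniformly; **planted** compounds draw the
  same way, then a deterministic top-up of
  $\lfloor (s-1) n M / N \rceil$ non-query genes is swapped for query
  genes, giving expected overlap $s \cdot nM/N$ (capped at $\min(M, n)$)
  for planting strength $s$. At $s = 1$ the top-up is zero, so planted and
  null compounds are exactly exchangeable — the property the calibration
  tests rely on;
* subtype gene sets with a configured overlap fraction against the query
  set, and a coverage guarantee (every universe gene annotated at least
  once) so the effective query size equals `query_size`;
* a single integer seed; replicated experiments derive per-replicate
  streams as `seed + replicate`.

**Default study conditions.** The defaults are a 2,000-gene universe, 200
compounds, a 100-gene query, 20 planted compounds at strength 3, and
$M \in [100, 1000]$. The size-law bounds were fixed a priori by a
closed-form power calculation: below $M \approx 100$ at these conditions, a
threefold overlap inflation is statistically indistinguishable from the
null at BH-corrected thresholds, which would contradict the recovery the
planting is defined to produce. The range therefore represents the
well-annotated compound stratum that dominates real ORA hits, rescaled to
the reduced universe. Real association tables differ in ways the generator
does not model — annotation bias, correlated gene sets, heavy-tailed size
laws — so passing calibration and recovery certify the implementation of
the statistic, not the biology of any particular database.

`null_pvalue_calibration()` (500 replicates at the default conditions in
the acceptance suite) checks that the fraction of null tests with
$p \le t$ stays below $t$ plus Monte-Carlo error — the hypergeometric test
is conservative because it is discrete — and that fewer than 7% of null
replicates report any BH discovery. `planted_recovery()` checks that
planted compounds are recovered at $q < 0.05$ (about 99% at the default
conditions, against the 90% the planting targets) with a false discovery
proportion among detections comfortably below the nominal 5%.

# Pipeline

`run_pipeline()` composes load → exclude → combine → enrich → blocklist →
consolidate → network → degree filter → stratify → (pathways) → export,
driven by one `pipeline_config()` (YAML-compatible, all defaults explicit).
Every stage logs counts in/out, so manual curation steps (gene exclusions,
blocklist removals) leave an audit trail, and the manifest records seed,
parameters, per-stage counts, and the md5 of each output; identical inputs
and seed reproduce byte-identical tables. The default gene exclusions —
ABCA4, ELOVL4, PROM1, BEST1 — are genes of distinct monogenic macular
dystrophies that contaminate literature-derived AMD lists; one printed
source truncates the second symbol to "ELOVL", but the accompanying protein
name ("elongation of very long-chain fatty acids protein 4") identifies
ELOVL4 unambiguously, which is the symbol the default uses.

# Problem sizes and limitations

The test suite and the acceptance script run entirely on synthetic data:
the small-universe sweeps are exhaustive ($N \le 12$ for the
hypergeometric oracle, $\le 10$ nodes for the brute-force graph metrics),
and the Monte-Carlo experiments use 500 null replicates and 30 planted
replicates at the default conditions — sizes chosen so the whole suite
certifies the statistics in a few minutes while keeping standard errors
small relative to the margins tested.

Known limitations: absolute p/q values of published hit tables are not
reproducible without the exact background universe and database snapshot
of the original enrichment service (only the structure, calibration and
ranking behaviour are testable); identifier handling is limited to case
normalization (no gene-ID mapping); the generator does not imitate real
CTD/STITCH marginal distributions beyond the configurable size law; and GO
annotations are tested as given, without ontology propagation.
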