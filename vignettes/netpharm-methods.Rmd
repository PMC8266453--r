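---
title: "Methods: network-pharmacology inference in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology inference in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The inference chain

`netpharm` models a multi-component medicine acting on a disease as a
chain of set and graph operations. The stages, and the statistical
assumptions behind each, are:

**ADME screening.** Drug-likeness is a conjunction of two binary
criteria. Lipinski violations are counted among MW > 500 g/mol,
logP > 5, HBD > 5, HBA > 10; `max_lipinski_violations = 0` by default
because the screening convention this package follows marks compounds
with even a single violation (e.g. a long-chain fatty acid whose only
excess is logP) as non-conforming, while the classic textbook rule
(`= 1`) remains one option away. Gastrointestinal absorption uses the
BOILED-Egg classification: high absorption iff the compound's
(TPSA, WLOGP) point falls inside the published
human-intestinal-absorption ellipse, whose coefficients — centre
(71.051 Å², 2.292), semi-axes 71.0405 Å² and 4.370, rotation −1.03°
(Daina & Zoete 2016) — are configuration values, not code constants.
Boundary points count as inside, with a 1e-9 relative tolerance so that
points constructed exactly on the ellipse are classified stably.
Precomputed GI classes (e.g. SwissADME exports) pass through unchanged;
a compound with neither a precomputed class nor both descriptors is a
hard error, never a silently defaulted class. Literature overrides
model the practice of restoring compounds with experimentally proven
bioactivity: an override guarantees retention and is recorded as the
decision's reason, so the retained set always partitions into
`passed_filters` and `literature_override`.

**Network model.** All networks are simple undirected graphs whose
nodes carry one of three roles (compound, target, pathway); edges may
carry a confidence score in [0, 1]. All centralities are hop-count
based — confidence scores never weight shortest paths, they only gate
which edges exist. Degree is the incident-edge count. Betweenness is
Freeman's fractional form, the sum over node pairs of
σ~st~(v)/σ~st~, unnormalized by default to match the NetworkAnalyzer
convention used by desktop network tools; a normalized mode (divide by
(n−1)(n−2)/2) and a raw path-count mode (no division by σ~st~) are
exposed because "number of shortest paths through a node" is ambiguous
between the two readings. Closeness is 1/Σd(i,u) over nodes reachable
from *i*; on disconnected graphs it is computed within each connected
component (no published rule exists for the disconnected case, and the
within-component reciprocal sum is the only reading that avoids
infinite distances), with isolated nodes assigned 0 by convention, and
a `(n_comp − 1)/Σd` normalized mode.

**Threshold selection.** Key-node rules compare a metric against its
population median or mean and keep nodes *strictly* above, following
the "higher than" phrasing conventional in this analysis style; with
non-strict comparison every tie at the threshold would enter, and on a
degenerate population the strict rule correctly selects nothing. The
median of an even-sized population is the arithmetic mean of the two
central values. Key disease targets use degree > median over the nodes
of the score-filtered PPI network — disease genes with no retained
interaction are excluded from the population, since a node that enters
no confident interaction carries no topological evidence. In the
C-T-P network, key compounds need degree > mean and key targets need
degree, betweenness and closeness all > mean; means are computed per
role (compounds against compounds, targets against targets) because
the three roles have structurally different degree distributions — a
network-wide mean mode is provided for sensitivity analysis.

**PPI filtering.** Combined scores > 0.7 (strict) are the conventional
high-confidence cut. Files on the 0–1000 integer dialect are detected
by any score exceeding 1 and divided by 1000; a score outside [0, 1]
after normalization is an error, as is a self-interaction.

**Enrichment.** Over-representation uses the exact hypergeometric
upper tail P(X ≥ k) via `stats::phyper`, numerically stable far beyond
the gene-universe sizes that occur here. The background defaults to the
union of all member genes of the loaded collection — the only
self-contained choice when the annotation service's universe is
unknown — and an explicit background overrides it; the query is
intersected with the background before testing. The
Benjamini–Hochberg family is *every* tested set, including those with
zero hits (excluding them would understate m and overstate
significance); zero-hit sets are simply not reported. Filtering is on
raw p < 0.05 by default, the convention for pathway collections, with
`filter_on = "adjusted"` for GO-style runs that quote corrected
p-values; both p columns are always emitted so either convention can
be compared. Rows sort by p then set id, so ties at a top-N cut are
deterministic.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage has inputs with known ground
truth. A single integer seed drives one named pseudo-random stream per
generator (the stream seed mixes the user seed with a hash of the
generator's name), so adding or re-running one generator never
perturbs another, and every generator is byte-reproducible.

* `gen_compound_table(n, violation_fraction)` draws descriptors from
  ranges typical of plant secondary metabolites (MW ~ U(150, 700)
  g/mol, HBD ~ Pois(3), HBA ~ Pois(6), logP ~ N(2, 1.5),
  TPSA ~ U(20, 250) Å², WLOGP ~ N(2, 1.5)) and then *forces* a
  designated 20% (default) of compounds to violate Lipinski (MW
  pushed above 500) while clamping the rest below every rule
  threshold, so the manifest's violation labels are exact.
* `gen_bipartite(n_compounds, n_targets, mean_degree)` defaults to the
  study scale of the motivating analysis — 55 compounds, 646 targets,
  mean 56.6 targets per compound — with per-compound target counts
  Poisson-distributed (truncated to [1, n_targets]); an exact-edge
  mode deals a shuffled permutation of targets across compounds first,
  so that a network with a prescribed edge total realizes every target
  node.
* `gen_ppi(n_nodes = 446, n_hubs = 10, hub_degree_boost = 5,
  edges_per_node = 9)` grows a preferential-attachment graph (new
  nodes attach with probability ∝ degree + 1) whose designated hubs
  receive a 5× attachment multiplier; scores are Beta(5, 2) stretched
  onto [0.4, 1.0], so roughly a tenth of edges fall at a 0.7 filter.
  The defaults mirror a disease PPI of ~446 proteins and ~3900
  edges.
* `gen_gene_sets(n_sets = 50, set_size_range = c(20, 80),
  background_size = 2000, query_size = 18)` plants one spiked set
  sharing 80% of an 18-gene query; with `spike = NULL` the query is a
  uniform background draw — the null used for calibration.

What the generators do *not* emulate: real chemical structures (ids
are placeholders), correlated descriptors (real MW and HBA are highly
correlated; the generator draws them independently), PPI topology
beyond hub planting (no clustering, no evidence channels), overlapping
pathway hierarchies (gene sets are independent uniform draws, whereas
real KEGG/GO sets nest and correlate). Consequently, passing recovery
tests show the pipeline's *rules* behave as specified — they do not
certify performance on real annotation structure, where correlated
gene sets make BH adjustment conservative in different ways and hub
recovery depends on study bias in the interaction database.

## Numerical and degenerate-input choices

* All symbol handling upper-cases and trims before comparison; no
  gene-alias dictionary is bundled (a user-supplied synonym map is
  applied during disease-target merging).
* Duplicate edges collapse with the first score winning; self-loops
  are errors everywhere.
* Ordering is always made deterministic by a lexicographic id sort
  after the primary key (p-value, degree), never left to hash or
  insertion order; reruns with identical inputs are identical.
* Empty populations (threshold selection over nothing, enrichment of a
  query disjoint from the background, a C-T-P role with no nodes) are
  errors, not empty results, because each indicates a broken upstream
  stage; an empty *overlap*, by contrast, is a legitimate scientific
  outcome and the pipeline reports it and skips the downstream stages.

## Test problem sizes

The suite verifies centralities against a brute-force oracle that
enumerates every shortest path explicitly, on 200 random graphs of 4–15
nodes, and the hypergeometric tail against full enumeration of all
draws for every feasible parameter combination with backgrounds up to
12. Recovery suites use 20 seeds (hub recall at the generator's
446-node default), 50 seeds (spiked-set top rank) and 200 seeds (null
calibration against the binomial envelope α + 2√(α(1−α)/200)). These
sizes keep the exhaustive oracles exact while exercising each rule well
past its boundary cases.

## Known limitations

Target prediction, descriptor computation and annotation are inputs,
not computations — the package deliberately has no web clients, so its
results are only as good as the supplied tables. The enrichment
background default (collection union) differs from annotation-service
universes, so absolute p-values are not comparable with those of
KOBAS-style servers, only the ordering and hit counts are. Centralities
are unweighted; a confidence-weighted betweenness would rank dense
high-score neighbourhoods differently. The tripartite key-node rule
inherits the usual caveat of mean thresholds on heavy-tailed degree
distributions: a single super-hub raises the mean and can shrink the
selected set.
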