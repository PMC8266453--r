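# netpharm

Network-pharmacology analysis for multi-component medicines in R.

Herbal preparations contain dozens of chemically diverse compounds, each
predicted to bind many protein targets. Network pharmacology asks which
of those compounds are plausibly active, which targets they share with a
disease, and through which pathways the compound–target interactions act
— by assembling everything into interaction networks and ranking nodes
by topology. `netpharm` implements that inference chain as composable,
tested functions:

1. **ADME screening** — a compound is kept when it conforms to
   Lipinski's rule of five (violations counted among MW > 500 g/mol,
   logP > 5, H-bond donors > 5, H-bond acceptors > 10; strict
   conformity by default, the classic one-violation tolerance by
   option) *and* has high predicted gastrointestinal absorption (the
   BOILED-Egg classification: the point (TPSA, WLOGP) inside the
   published human-intestinal-absorption ellipse). Compounds failing
   either filter can be restored by a literature-evidence override.
2. **Compound–target network** — a bipartite graph of screened
   compounds and their predicted targets, summarised by per-role mean
   degrees (targets per compound, compounds per target).
3. **Disease targets and PPI** — disease gene lists merged across
   sources with provenance, a STRING-style protein–protein interaction
   edge list filtered at combined score > 0.7 (the 0–1000 integer
   dialect is auto-detected), and *key* disease targets selected as the
   nodes whose degree strictly exceeds the filtered network's median
   degree.
4. **Overlap and enrichment** — the intersection of compound targets
   with key disease targets is tested for over-representation against
   flat gene-set collections (GMT) with the hypergeometric upper tail
   `P(X ≥ k)` for `X ~ Hypergeometric(N, K, n)`, corrected by
   Benjamini–Hochberg across all tested sets.
5. **Compound–target–pathway (C-T-P) network** — a tripartite graph of
   compounds, overlap targets and the top enriched pathways. Key
   compounds have degree strictly above the compound-role mean; key
   targets have degree, betweenness *and* closeness above the
   target-role means. Centralities are hop-count based: Freeman
   betweenness (fractional shortest-path transit) and closeness as the
   reciprocal summed distance within a node's component.

A synthetic-data module (`gen_compound_table`, `gen_bipartite`,
`gen_ppi`, `gen_gene_sets`) generates inputs with planted structure —
Lipinski violators, preferential-attachment PPI graphs with boosted
hubs, gene-set collections with a spiked over-represented set — plus
ground-truth manifests, so every stage is testable end to end without
external web services.

## Worked example

Screening the bundled 55-compound *Hemerocallis fulva* (daylily flower)
descriptor table, in which eleven compounds fail a filter but carry a
literature override:

```r
library(netpharm)
tbl <- read_compound_table(system.file("extdata",
    "hf55_compounds_synthetic.tsv", package = "netpharm"))
summary(screen_compounds(tbl))
#> $n_input
#> [1] 55
#> $n_retained
#> [1] 55
#> $n_override
#> [1] 11
```

A compound–target network at that study's scale (55 compounds, 646
targets, 3112 prediction edges):

```r
g <- gen_bipartite(55, 646, seed = 1, n_edges = 3112)
str(network_summary(build_bipartite(g$pairs)))
#> $ n_nodes             : num 701
#> $ n_edges             : num 3112
#> $ nodes_per_role      : Named int [1:2] 55 646
#> $ mean_degree_per_role: Named num [1:2] 56.6 4.8
```

so each compound hits 56.6 targets on average and each target is hit by
4.8 compounds — the multi-component, multi-target signature.

Enrichment of a synthetic 18-gene query against a collection with one
planted set (14 of the 18 query genes fall in `SET001`):

```r
gs <- gen_gene_sets(seed = 42)
enrich(gs$query, gs$collection, filter_on = "adjusted", alpha = 0.05)
#>   set_id hit_count set_size      p_value   p_adjusted
#> 1 SET001        14       59 7.792157e-21 3.896078e-19
```

The full pipeline is one call, `run_netpharm()`, returning a classed
object with every intermediate artifact, and `write_run_report()`
persists them (TSV/SIF/GraphML/JSON).

## Notes on the bundled fixtures

`inst/extdata/hf55_compounds_synthetic.tsv` carries the published
identity, formula, molecular weight, GI class and Lipinski-conformity
flag of each compound; the HBD/HBA/logP descriptor columns are
reconstructed from the compounds' known structures (they are not part
of the published table), hence the `synthetic` label. The overlap gene
list and the top-15 pathway table are published values used as inputs.
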