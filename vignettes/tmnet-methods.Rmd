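---
title: "Mining disease-material associations and network pharmacology with tmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease-material associations and network pharmacology with tmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmnet)
```

## The problem

Multicomponent traditional-medicine prescriptions pair one or more diseases
with a set of medicinal materials (mostly plants, occasionally animal or
mineral products). Across a curated corpus of such prescriptions, the
question is which disease–material pairings recur more often than chance, and
whether the bioactive constituents of a recurrent material plausibly act on
the disease through known molecular networks. `tmnet` implements that whole
chain: market-basket association mining over prescriptions, a bipartite
disease–material network, protein–protein interaction (PPI) centrality and
hub extraction, random-walk-with-restart (RWR) disease prioritization on a
heterogeneous compound–target–disease network, and hypergeometric
over-representation analysis (ORA) of target genes.

Because curated prescription corpora and the commercial network resources
behind such studies are generally not redistributable, every input has a
synthetic generator with planted, exactly realized ground truth. The package
is therefore fully exercisable — and testable — offline.

## The basket model and rule metrics

Each prescription is a transaction: a set of disease labels plus a set of
material labels (the two namespaces are disjoint; presence/absence only,
never dosage). The corpus is encoded as a binary matrix with one row per
prescription and one column per catalog item. For a rule $X \Rightarrow Y$
with a disease antecedent $X$ and a material consequent $Y$, counted over $N$
transactions:

$$\mathrm{supp}(X \Rightarrow Y) = \frac{n_{XY}}{N}, \qquad
\mathrm{conf}(X \Rightarrow Y) = \frac{n_{XY}}{n_X}, \qquad
\mathrm{lift}(X \Rightarrow Y) = \frac{\mathrm{conf}(X \Rightarrow Y)}{n_Y / N},$$

where $n_{XY}$, $n_X$ and $n_Y$ count transactions containing both items, the
disease, and the material. Lift 1 is statistical independence; lift above 1
means the material is used disproportionately for that disease. A high-lift,
modest-confidence rule marks a disease-specific material; a high-confidence,
low-lift rule marks a broadly used material.

Frequent itemsets are found by the classic level-wise apriori search:
frequent singletons from column counts, candidate pairs joined from frequent
singletons, and (at deeper levels, available via `max_rule_length`) candidate
pruning by downward closure before counting. At the default rule length of 2
the counting pass is a single cross-product of the frequent-item submatrix,
which is exactly the level-2 apriori count. Rules are emitted only for
frequent {disease, material} pairs and filtered with *inclusive* thresholds:
support $\ge$ `min_support` and confidence $\ge$ `min_confidence`.

Defaults are `min_support = 0.003` (0.3%) and `min_confidence = 0.10`. A
threshold statement like "0.3 and 10%" is only coherent with mined supports
in the 0.4–1.6% range if the support cutoff is 0.3 *percent*, so that is the
default reading; both values are plain arguments to `mining_config()`.

Reports render support and confidence as percentages and lift at 2 decimal
places using round-half-up (`round_half_up()`), the convention of published
summary tables; internal values keep full precision.

### Reconstructing counts from printed metrics

Published rule tables print (support %, confidence %, lift) at 2 decimals but
not the underlying counts. `reconstruct_counts()` inverts the three equations
sequentially with half-up rounding — $n_{XY}$ from support, then $n_X$ from
confidence, then $n_Y$ from confidence/lift — and then *verifies* the
candidate counts by recomputing all three metrics and requiring agreement at
2 decimals (tolerance 0.005). A row with no consistent integer solution
raises an infeasibility error rather than being silently repaired. The
bundled table (`published_rule_metrics()`, 91 rows over ten diseases at
$N = 505$) reconstructs exactly in every row, and the test suite round-trips
each row through the generator and the miner.

## The synthetic prescription generator

`synth_prescriptions()` realizes planted rules *exactly*, never in
expectation: for each planted disease the generator reserves a block of
$n_X$ transactions, places the material into the first $n_{XY}$ of them, and
places the material's remaining $n_Y - n_{XY}$ occurrences in filler
transactions whose diseases are outside the planted set, so no planted
margin or joint count can drift. Background noise adds non-planted materials
with a small per-cell probability (`noise_rate`, default 0.01, giving a
realistic handful of extra materials per prescription at the default catalog
sizes); fillers that would otherwise be empty receive one material by
cycling the background pool, which avoids accidentally manufacturing a
repeated disease–material pair. Defaults (505 transactions, 106 diseases,
567 materials, one disease per prescription) emulate the scale of a curated
national corpus; all are arguments.

What the generator does *not* emulate: real corpora have heavy-tailed
material frequencies, correlated material co-usage (recipes), and
multi-disease prescriptions. Passing tests on synthetic data therefore
demonstrate correctness of the computations and exact recovery of planted
structure, not robustness to the full messiness of curated ethnobotanical
data.

## Bipartite network and radar tables

`build_rule_network()` turns surviving rules into a strictly bipartite
igraph: one node per label, one edge per rule, lift as edge weight and
degree as node attribute (so node size in a drawing reflects breadth of
use). `radar_table()` gives the per-disease view behind a radar chart:
confidence and lift per material plus standardized columns. Published
figures rarely define "standardized", so the default is the within-chart
z-score and min–max scaling to $[0,1]$ is available via `scheme`; the choice
is recorded in the table's `standardization` attribute, and a zero-variance
column standardizes to 0 by convention.

## PPI centrality and hubs

`merge_ppi_sources()` combines tagged edge lists into one simple undirected
graph: directed records are symmetrized, self-loops dropped with a message,
and unordered duplicates collapsed while concatenating their source tags.
The merge is order-independent.

`centrality()` reports raw degree (incident-edge count, not normalized — the
only reading under which integer percentile thresholds on a ~17k-node
network make sense) and eigenvector centrality. The eigenvector score is the
principal eigenvector of the adjacency matrix of the *largest connected
component*, L2-normalized, with all other nodes scored 0; published analyses
are typically silent on this point and the dominant-eigenvector convention
is the defensible default. Numerically the power iteration runs on
$A + I$ rather than $A$: the shift leaves the Perron vector unchanged on a
connected graph but makes the spectrum strictly positive, so bipartite-like
components (eigenvalues $\pm\lambda$) cannot cause oscillation. Convergence
is declared when successive L2-normalized iterates differ by less than `tol`
(default 1e-10), with a hard error, not a silent result, at `max_iter`.

`percentile_thresholds()` ranks nodes per measure and takes the score at
rank $\lceil f\,|V|\rceil$ as the top-$f$ threshold, keeping all tied nodes
(tie handling is undefined in most published analyses; inclusion is the
conservative choice). `extract_hubs()` intersects a query target list with
the top-1% sets of *both* measures; the hub set is monotone in the fraction.

`synth_ppi()` provides the test bed: a Barabási–Albert preferential-
attachment graph plus optional planted super-hubs wired to a fixed fraction
(default 20%) of the ordinary nodes, which provably lands them in the top
percentile of both measures at the default 2000-node scale.

## Random walk with restart

On the heterogeneous network (protein, compound and disease nodes; PPI,
compound–target and target–disease edges; positive weights), RWR iterates

$$p \leftarrow (1 - r)\,W p + r\,p_0$$

with $W$ the column-normalized adjacency (the walker steps to a uniformly
random — or weight-proportional — neighbor) and $p_0$ the seed distribution
over therapeutic targets. Probability mass reaching a degree-zero node is
redirected to $p_0$, so every iterate is exactly a probability distribution.
Iteration stops when the L1 change drops below `tol = 1e-10` (residuals
shrink geometrically at rate at most $1 - r$); `restart = 1` returns the
seeds unchanged. The restart probability defaults to $r = 0.7$, the common
network-propagation choice; published applications of RWR frequently omit
the value, so it is exposed and recorded in output metadata rather than
treated as canonical. `rank_diseases()` then sorts disease-type nodes by
score, breaking exact ties lexicographically and flagging them.

Correctness is checked against the closed form
$p = r\,(I - (1-r)W)^{-1} p_0$ on random graphs; type-stratified transition
weighting is deliberately not applied by default because no published
parameterization exists to copy.

## Over-representation analysis

`ora()` tests each gene set of size $K$ against the mapped query of size $n$
in a universe of size $N$ (default: the union of library members;
configurable) with the upper-tail hypergeometric probability
$P(\text{overlap} \ge k)$, computed via `phyper`, and adjusts across terms
with Benjamini–Hochberg. Filtering is inclusive at `alpha = 0.05` on the
adjusted value. GMT parsing collapses duplicate members, skips empty sets
with a warning, and rejects duplicate set names. Ranked gene-set enrichment
(GSEA-style running statistics) is intentionally out of scope; the
reported-significance semantics of the upstream analyses correspond to ORA
with BH at 0.05.

## The pipeline

`run_pipeline()` wires the stages (simulate → mine → network → hubs → rwr →
enrich) with one resolved configuration persisted as YAML next to the
outputs. All tabular outputs are headered TSV; networks are GraphML plus
node/edge TSV; nothing written contains a timestamp, so a rerun under the
same resolved config is byte-identical. Referenced input paths are validated
before any output is created. A thin command-line wrapper lives at
`inst/cli/tmnet-pipeline.R`.

## Problem sizes and numerical choices, summarized

* Mining verification: exhaustive pair enumeration agrees with the miner on
  500 random databases of up to 200 transactions and 30 items; study-scale
  runs use the default 505 × (106 + 567) layout.
* Eigenvector centrality: dense eigendecomposition oracle on graphs up to 50
  nodes at 1e-6; planted-hub recovery on 2000-node scale-free graphs.
* RWR: direct linear solve oracle on graphs up to ~30 nodes at 1e-8.
* ORA: 200,000-draw permutation oracle on a 200-gene universe, agreement
  within 3 Monte-Carlo standard errors.
* Ties: descending confidence, then lift, then label for rules; lexicographic
  with a flag for equal RWR scores; all tied nodes kept at a centrality
  threshold.
* Degenerate inputs fail loudly with classed conditions
  (`tmnet_validation_error`, `tmnet_infeasibility`,
  `tmnet_convergence_error`, ...), never with silent repairs.

## Known limitations

* Rules are single-disease ⇒ single-material; multi-antecedent rules and
  closed/maximal itemset compression are out of scope.
* The generators use opaque label vocabularies and do not model correlated
  material co-usage, so synthetic lift distributions are better behaved than
  real ones.
* Eigenvector centrality outside the largest component is defined as 0; on
  networks whose interesting structure lives in a secondary component,
  analyze components separately.
* ORA results depend on the gene-set library and universe supplied; the
  package ships no curated pathway libraries.
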