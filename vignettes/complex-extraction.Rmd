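---
title: "Knowledge-driven protein complex extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-driven protein complex extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Protein complexes — groups of proteins that interact to carry out a
biological activity — appear in a protein–protein interaction network
(PPIN) as dense subnetworks. Extracting them from high-throughput
interaction data is complicated by the data's two systematic defects:
spurious reported interactions (false positives, FP) and real interactions
the screens missed (false negatives, FN). Which purification strategy and
which clustering algorithm suit a given network depends on measurable
properties of that network, and `complexpert` encodes that expertise as an
executable decision system: a small forward-chaining rule engine analyses
the input, proposes strategies and tools with explicit rationales, runs
them, audits the consequences, and records a backtrackable workflow trace.

The package ships a 34-protein, 90-interaction subset of the
*Saccharomyces cerevisiae* DIP network (actin cytoskeleton machinery) as
its worked example; every algorithm also runs on synthetic networks from
the built-in generators.

## The decision model

Working memory holds *facts* — `(predicate, slots)` pairs such as
`core_fraction(value = 0.744)` — asserted by the input analysis, by the
user, or by tool results. *Rules* are `IF precondition THEN action`
productions, each owned by exactly one *decision module*; modules form a
tree (a root supervising preprocessing and clustering children, plus three
registered but inactive specialist modules). Only rules of the focused
module fire; a module that exhausts its advice returns focus to its
parent. Conflict resolution is salience-descending with rule-id
tie-breaks, and *refraction* guarantees a rule fires at most once per
distinct fact match, so inference is deterministic and terminates.

The rule content, in brief:

* **R1** — the degree distribution of most cellular networks approximates
  a power law; if the input network is *not* scale-free, its geometry is
  suspect and preprocessing is proposed.
* **R2 / R2′** — roughly half the interactions from high-throughput
  screens may be false positives (the constant `0.5` is stored and
  documented). If the curated-core fraction exceeds that rate, deletion
  would endanger core interactions, so FN *addition* is advised and FP
  deletion suppressed; otherwise deletion is advised.
* **R4** — a chosen strategy is matched to the registered tool with the
  lowest computational cost rank for that purpose, with proposed
  parameters.
* **R5** — if a purification step deleted core interactions, warn and
  advise changing strategy or parameters.
* **R3** — once the network is preprocessed, MCL is proposed for
  clustering: MCODE is noise-sensitive, MCL and RNSC perform similarly on
  noisy or purified networks, and MCL is the fastest of the three.
* **R6** — a finished clustering triggers a visualisation export (SIF plus
  node-attribute table).

User decisions (`accept`, `override:<alternative>`, `reject`, `rollback`)
are an injectable source: interactive at a prompt, scripted in tests.
Overrides first save a checkpoint — a deep snapshot of working memory,
networks, focus and trace cursor — and rollback restores it exactly,
keeping the abandoned branch visible in the trace marked `abandoned`.
The trace itself is a three-layer DAG (data states / strategies inside
module boundaries / executed tools) exported as canonical JSON (the
round-trippable form), GraphML, or DOT with module boundaries as clusters.

## The algorithms

**Defective-clique FN completion.** A defective clique is a near-clique
missing exactly one edge. A non-adjacent pair `(u, v)` is predicted as a
missing interaction when the common neighbourhood of `u` and `v` contains
a clique of at least `min_common` proteins, so adding `(u, v)` completes a
clique of `min_common + 2` proteins. The search enumerates cliques inside
each common neighbourhood only — at curated-subnetwork scale these are
tiny, so no global clique enumeration is needed. Predictions are ordered
by completed-clique size with lexicographic tie-breaks.

**FP filtering by topological scores.** Three interchangeable scores:
raw edge betweenness (fractional credit across tied shortest paths;
high = suspect, because FP edges tend to bridge unrelated regions), an
edge-level clustering coefficient (mean of the endpoint coefficients;
low = suspect), and their combination (geometric mean after min–max
normalisation to [0, 1] over the network). Selection is either top-k by
rank or by threshold, with deterministic lexicographic tie-breaks and an
optional `protect_core` guard. Removal never drops nodes, and every
purification step can be audited: deleting even one curated core
interaction yields a `warn` verdict.

**MCL.** The column-stochastic transition matrix of the network (unit
self-loops added) is alternately expanded (matrix square — flow spreads)
and inflated (entry-wise power with column renormalisation — strong flow
strengthens), pruning entries below `1e-5`, until the largest entry change
falls below `1e-6`. Clusters are the connected components of the limit
matrix's support; overlapping attractor systems merge, so the output is
always a partition. Nodes are indexed in sorted order, making the result
independent of input record order.

**MCODE.** Vertex weight = (highest k-core number of the closed
neighbourhood) × (density of that core subgraph). Complexes grow from the
highest-weight unvisited seed, recruiting neighbours whose weight is
within `vwp` of the seed's; haircut iteratively removes members with fewer
than two in-complex neighbours (so the invariant holds after termination,
not merely after one pass); optional fluff absorbs boundary neighbours
with dense closed neighbourhoods. The result is a ranked complex list
(density × size), not a partition.

**RNSC.** Cost-based partitioning. The naive cost counts each bad
relation once: `C = Σ_v α_v / 2` with
`α_v = #non-neighbours of v inside v's cluster + #neighbours outside`.
The scaled cost divides each `α_v` by `|N[v] ∪ C_v|` and multiplies by
`(n − 1)/3`, de-emphasising hubs. From a seeded random partition the
search applies the best single-vertex move (steepest descent over all
vertex–cluster moves, one empty cluster always available), a tabu list
blocks immediate reversals, a random diversification move fires
periodically, and each phase stops after `max_no_improve` non-improving
steps — naive phase first, then the scaled phase from the naive optimum.
The seed is a mandatory parameter (no hidden global RNG) and restart `r`
uses `seed + r − 1`, so runs are exactly reproducible.

**Enrichment.** Cluster coherence is scored by the upper-tail
hypergeometric probability of drawing at least `k` annotated proteins in a
cluster of `n` from a universe of `N` with `K` annotated, computed by
direct summation in log space. Annotations come from a local term→protein
table (the live ontology service the original workflow called is neither
offline-reproducible nor stable over time). Per cluster the
minimal-p term is reported; clusters whose best p exceeds the `alpha`
cutoff print as `> alpha`, the usual suppression convention. No
multiple-testing correction is applied, matching the workflow the package
models.

## Frozen parameters and how they were chosen

All knowledge-base defaults live in `R/constants.R`; the committed sweep
(`scripts/calibration.R`, with `calibration_sweep()` as a first-class
operation) reproduces each choice on the packaged network.

| Parameter | Default | Basis |
|---|---|---|
| `min_common` (defective cliques) | 4, capped at the 1 best prediction | Sweep: candidate pairs shrink 23 → 2 → 0 for λ = 3, 4, 5; no raw λ gives exactly one, so λ = 4 with a best-prediction cap (largest completed clique, lexicographic ties) reproduces the one-edge augmentation. |
| FP filter policy | betweenness, top-k = 3 | A dispersion cutoff (mean + 2 sd) selects only one edge on this network; rank-based selection is scale-free across networks and reproduces the three-edge removal. |
| MCL inflation (yeast) | 2.2 | Sweep 1.8–3.0: agreement with the reference cluster sets saturates at inflation 2.2 (output is identical through ≥ 2.5); 2.0 remains the generic default. |
| MCODE | vwp 0.2, haircut on, fluff off | The original algorithm's standard operating point; the sweep shows no vwp changes the verdict on the reference complex (below). |
| RNSC | 50 restarts, tabu 3, diversify every 20, stop after 30 idle steps | Best-of-50 is stable on the 34-node network (the reference quadruple appears in every restart) and completes in seconds. |
| High-throughput FP rate | 0.5 | Literature estimate encoded in R2/R2′. |
| Scale-free criterion | log–log least squares, R² ≥ 0.80, exponent ∈ [1.5, 3.5], n ≥ 20 | Must reject a 34-node curated subnetwork while accepting preferential-attachment graphs; maximum-likelihood tail fitting is fragile at tiny n, so the criterion object is pluggable. Networks below 20 nodes get "not assessable" rather than a verdict. |

## Synthetic data: what it emulates, what it does not

`generate_ba_graph` (preferential attachment) supplies scale-free degree
structure for the criterion tests; `generate_planted_complexes` plants
dense groups (`p_in`) in background noise (`p_out`) with ground truth for
recovery scoring (best-match Jaccard); `perturb_network` injects FP/FN
noise and returns the exact delta; `generate_annotations` aligns one term
per planted cluster at a chosen coverage. All generators are pure
functions of their parameters and seed. They emulate degree structure,
planted density contrast, and annotation alignment — not the biological
correlations of real interactomes (hub-complex entanglement, shared
subunits between complexes, experiment-specific error structure), so a
passing recovery test certifies algorithmic behaviour, not field
performance.

The packaged core-interaction list is a synthetic stand-in (DIP's curated
core labels are not redistributable): 67 of the 90 interaction IDs are
flagged, fixed so the curated fraction (0.744) and the audit outcome of
the deletion branch (2 core among 3 removed) match the documented
workflow. Rule tests assert behaviour relative to the 0.5 constant, never
a specific core assignment.

## Numerical choices and degenerate inputs

MCL prunes below `1e-5` and renormalises; a fully pruned column is parked
on its own diagonal so the matrix stays stochastic. Convergence is the
max-norm of the iterate difference below `1e-6`, capped at 200 iterations
with a `converged` flag on best-effort output. Isolated nodes become
singletons. RNSC tracks costs incrementally (O(deg) naive deltas; scaled
deltas recompute only the affected clusters' terms) and compares with a
`1e-9` slack to keep float drift from flipping accept decisions. Empty
networks parse to empty objects rather than errors; empty annotation maps
report every cluster above the cutoff; a network below the scale-free
criterion's minimum size yields `NA` (not `FALSE`). All
cluster orderings and tie-breaks are lexicographic after size, so every
output is stable across platforms.

## Known limitations

* The reference system-output table for the MCL workflow cannot be
  reproduced exactly, by this or any flow-based implementation: as printed
  it contains a two-protein cluster whose members are not even adjacent
  (they share only a neighbour the table omits), a protein listed without
  its sole network neighbour, and a protein excluded although all four of
  its neighbours are members. Five proteins are absent from the printed
  table altogether; our partition at the frozen defaults matches two of
  the five reference clusters exactly and the remainder up to exactly
  those five proteins. The acceptance suite asserts the published sets
  faithfully and documents the failure rather than loosening the check.
* The narrated FN prediction names a protein pair that already appears in
  the input table; the completion here therefore adds a different,
  best-supported pair. Downstream MCODE output differs accordingly.
* Betweenness recomputation is O(VE) per filtering pass; the toolkit
  targets curated subnetworks (tens to low hundreds of proteins), not
  proteome-scale graphs.
* Enrichment p-values depend entirely on the supplied annotation map and
  are not comparable to values computed against a live, versioned
  ontology database.

## Problem sizes exercised

The test suite works at desk scale by design: oracle comparisons
enumerate paths, triples, cliques and partitions on graphs of 5–10 nodes
across fixed seeds; recovery tests use 4 planted clusters of 10 at
`p_in = 0.9 / p_out = 0.05` (MCL, and RNSC with 20 restarts); scenario and
acceptance runs use the packaged 34-protein network with RNSC best-of-50.
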