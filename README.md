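# complexpert

Knowledge-driven extraction of protein complexes from protein–protein
interaction (PPI) networks.

High-throughput interaction screens produce networks that are both noisy
(false-positive edges) and incomplete (false-negative edges), and the right
combination of purification and clustering depends on measurable properties
of the network at hand. `complexpert` packages that expertise as an
executable decision system for computational biologists working with
curated PPI subnetworks:

* a **forward-chaining rule engine** (facts, salience, refraction, a tree of
  decision modules) that analyses the input — size, curated-core fraction,
  scale-free test — and proposes strategies and tools with explicit
  rationales, pros/cons and parameters;
* **network purification**: false-negative prediction by *defective-clique
  completion* (a non-adjacent pair `(u,v)` whose common neighbourhood
  contains a λ-clique completes a (λ+2)-clique missing exactly one edge) and
  false-positive filtering by *edge betweenness*, endpoint clustering
  coefficient, or their normalised geometric mean, with a **core-preservation
  audit** that warns whenever a manually curated interaction is deleted;
* re-implementations of the three standard complex-extraction algorithms —
  **MCL** (flow simulation: expansion `M²`, entry-wise inflation `M^r` with
  column renormalisation), **MCODE** (k-core-based vertex weighting, seeded
  complex growth, haircut/fluff post-processing) and **RNSC** (tabu search
  minimising the naive cost ½Σ_v α_v and its neighbourhood-scaled variant);
* **hypergeometric enrichment** of clusters against a local term→protein
  annotation map (upper-tail P(X ≥ k) for k of n annotated in a cluster,
  K of N in the universe, summed in log space);
* a three-layer, backtrackable **workflow trace** (data states / strategies
  inside module boundaries / executed tools) with checkpoints, rollback, and
  JSON/GraphML/DOT export;
* **synthetic generators** (preferential-attachment graphs, planted
  complexes, FP/FN perturbation, aligned annotations) so everything is
  testable offline, plus a packaged 34-protein, 90-interaction yeast DIP
  subnetwork with a synthetic core-interaction list.

## Worked example

```r
library(complexpert)

net <- annotate_core(dip_yeast_subnet(), dip_core_ids())
print(net)
#> PPI network: 34 proteins, 90 interactions, core fraction 0.744

is_scale_free(net)
#> log-log fit: gamma=0.68, R2=0.51 (log-log LS fit: R2>=0.80,
#>   gamma in [1.5,3.5], n>=20) -> not scale-free
```

The network is not scale-free and nearly three quarters of its
interactions are curated, so the engine advises completing false negatives
rather than deleting edges. Running the whole decision loop with every
suggestion accepted:

```r
sc <- run_scenario(net)
print(sc)
#> complex-extraction scenario run
#>   tools executed: detect-defective-cliques -> mcl -> cytoscape-export
#>   final network: 34 proteins, 91 interactions
#>   clusters: 8 (+0 singletons)
```

The defective-clique tool adds one predicted interaction (90 → 91 edges);
MCL at the yeast default inflation (2.2) then partitions the augmented
network; the clustered network is exported as SIF with a node-attribute
table. `export_trace(sc$trace, "dot")` draws the run as a workflow grouped
by decision module.

The pieces also work standalone:

```r
pred <- predict_false_negatives(net, defective_clique_params(4, max_predictions = 1))
#>      a       b completed_clique
#> 1 app1 yor284w                6
aug <- apply_additions(net, pred)                      # 91 interactions

flag_false_positives(aug)                              # default: top-3 betweenness
#>      a     b    score
#> 1 app1  crn1 40.16667
#> 2 cap2 las17 35.79405
#> 3 abp1  cla4 34.39048
red <- remove_edges(aug, flag_false_positives(aug))    # 88 interactions
core_preservation_audit(aug, red)
#> core preservation audit: warn (2 core interaction(s) have been deleted;
#>   consider changing strategy and/or modifying parameters)
```

The audit is what fires the engine's warning rule on the deletion branch:
scripted decisions (`decisions = c("accept", ..., "override:delete-fp-ppis",
"accept", "rollback", ...)`) replay that detour, roll back to the
checkpoint, and resume the completion branch.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/complexpert.R analyze --edges inst/extdata/dip_yeast_subnet.tsv \
    --core inst/extdata/dip_core_ids_synthetic.txt
Rscript inst/cli/complexpert.R run-scenario --edges inst/extdata/dip_yeast_subnet.tsv \
    --core inst/extdata/dip_core_ids_synthetic.txt --accept-all --trace-out trace.json
```

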