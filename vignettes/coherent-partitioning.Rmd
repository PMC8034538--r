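---
title: "Coherent partitioning of PPI networks into biclique-spanned complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherent partitioning of PPI networks into biclique-spanned complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(coherentpartition)
library(igraph)
```

## The model

Protein complexes observed in curated catalogues span a density continuum:
a bait protein pulled down with many preys induces a star; partially
resolved subcomplexes induce complete bipartite patterns; tight multimers
induce cliques. A single graph class covers all of these: a graph is
**biclique spanned** when its nodes admit a split into two non-empty parts
with every cross-part edge present, within-part edges unconstrained. Two
facts drive everything in this package:

1. *Complement characterization.* G is biclique spanned ⇔ its complement
   G⁻ is disconnected. (The parts of the bipartition are unions of
   components of G⁻.) This turns an exponential bipartition search into a
   connectivity check, and it is how `is_biclique_spanned()` is computed;
   the test suite cross-checks it against literal bipartition enumeration
   on thousands of small random graphs.
2. *Diameter bound.* Any two nodes of a biclique-spanned graph are at
   distance ≤ 2 (same part: both adjacent to the whole other part; other
   part: adjacent directly). Hence any biclique-spanned subgraph containing
   a node u lies inside u's second neighborhood N₂(u), and the search for
   candidates can be local.

A **coherent partition** of a network is a partition of its node set in
which every block induces a biclique-spanned subgraph; it is rendered by
removing the blocks' crossing edges (the *edge cut*), and optimal when that
cut is smallest. Finding the optimum is NP-hard, so `coherent_partition()`
is a greedy approximation:

* for each node u of a surviving component, `candidate_cluster()` builds
  N₂(u), takes the complement H⁻ of the induced subgraph, and
  * if H⁻ is disconnected, N₂(u) itself is the candidate;
  * otherwise a node cut of H⁻ is removed from the candidate — removing a
    vertex cut of the complement disconnects it, so what remains is
    biclique spanned;
* candidates are scored by the cut ratio (Eout/Ein)·(1/d) with density
  d = 2·Ein/(|V|(|V|−1)); the component's minimum-score candidate becomes a
  cluster, its boundary edges join the cut, its nodes leave the working
  graph;
* components are recomputed and the loop repeats until the graph is empty.

Nodes removed as complement cuts are *not* discarded: they stay in the
working graph and are clustered later, so the output always covers every
protein. Isolated nodes score the sentinel `Inf` (the score divides by
Ein), so singleton clusters are only emitted when a component has shrunk to
a single node.

## Tunables and conventions

The method is parameter-free in the sense that nothing needs fitting to a
particular network. The implementation still fixes a few choices:

* `exact_cut_threshold` (default 20 nodes): complements up to this size
  get an exact enumeration of all minimum-size vertex separators (max-flow
  based), each scored, best kept. Above it, articulation points (size-1
  cuts) are tried, then the heuristic of removing the neighbors of a
  minimum-degree node of the complement — always a valid cut, since it
  isolates that node. 20 keeps the exact path active on all desk-scale
  tests while bounding worst-case work on hub-dominated neighborhoods.
  (The classical inequality runs connectivity ≤ minimum degree, so the
  heuristic cut is an upper bound on the minimum cut, not the minimum
  itself — hence "heuristic".)
* *Determinism without a seed.* All ties — among candidate scores, among
  minimum cuts, among clusters — are broken by (smaller score, larger
  cluster, lexicographically smallest member set), under C-collation
  string order. Any minimum-score candidate would be a correct choice;
  fixing one makes runs byte-reproducible, which the tests rely on.
* *Per-component greediness.* One cluster is removed per connected
  component per round. Components are independent, so this matches a
  global minimum-score rule in outcome while allowing the per-component
  scans to be parallelized in principle (none is attempted here).
* Evaluation conventions: Jaccard matches are strict (> 0.5), fraction
  match is strict (> 0.25) and counts matched gold complexes by default
  (`count = "pred"` flips it), neighborhood-affinity matches are inclusive
  (≥ θ); MMR uses a maximum-*weight* matching with overlap-score weights
  ω(A,B) = |A∩B|²/(|A||B|) — the same formula backs FRM and the affinity
  score; all ratio measures return 0 rather than NaN on empty overlap, so
  the composite score stays defined; the default report θ is 0.25, the
  conventional affinity threshold, while `mmr_fplus_curve()` sweeps θ over
  a 0.05-step grid. Separation is computed as the geometric mean of the
  complex-wise and cluster-wise averages of (t²ᵢⱼ)/(tᵢ.·t.ⱼ), the original
  convention of its authors. Modularity requires a non-overlapping
  partition covering the network and errors otherwise.

## What the synthetic generator emulates — and what it does not

`plant_network()` states a simple world: ground-truth complexes are
disjoint biclique-spanned components (stars, bicliques, cliques, or
bicliques with random within-part extras), and experimental noise consists
of spurious *inter*-complex edges sampled uniformly without replacement.
Noise is never planted inside a complex, so the planted truth remains
biclique spanned at any noise level and "perfect recovery" is always
well-defined. `fixture_plant_specs()` fixes the suite used throughout
validation: stars with 2–8 leaves, bicliques up to parts (4, 5), cliques up
to 7 nodes, and mixtures; low-noise variants add 4 noise edges (roughly
5–10% of planted edges on these fixtures).

Real PPI data differ in ways this world does not model: missing intra-
complex edges (false negatives), shared subunits between complexes
(overlap), degree-dependent rather than uniform noise, and study bias. A
green zero-noise recovery test therefore establishes correctness of the
algorithmic machinery — every component that *is* biclique spanned is
recognized and returned free of charge, score 0 — not field performance on
noisy networks. The degradation test (mean composite score non-increasing
across noise levels over 20 seeds each) checks the direction of the
response to noise, not its magnitude.

## Numerical and degenerate-input choices

* Single-node graphs count as (degenerately) biclique spanned; the empty
  graph is rejected by `is_biclique_spanned()` but yields an empty
  partition in `coherent_partition()`.
* Complete graphs have no vertex cut; `min_node_cut()` refuses them (and
  graphs with < 3 nodes). Inside the partitioner this case cannot arise:
  a complement under scrutiny is connected with ≥ 3 nodes and always has a
  non-edge.
* Score comparisons use exact floating-point equality for tie detection.
  Tied scores in practice arise from symmetric candidates whose scores are
  computed by identical arithmetic, so this is stable; near-ties that are
  not exact ties are treated as ordered, which is harmless since any
  minimum-score candidate is acceptable.
* Cluster scores use `Inf` (not a large constant) for the Ein = 0
  sentinel, so ordinary comparisons do the right thing.
* Graph loading collapses duplicate edges and self-loops silently apart
  from an informational message, since raw PPI exports commonly contain
  both; a third edge-list column (confidence) is ignored with a message
  rather than an error.

## Known limitations

* The greedy is not optimal, and not even pointwise monotone: on two
  4-cliques joined by a bridge, every clique node's second neighborhood
  absorbs the far bridge endpoint into a valid biclique-spanned candidate,
  so the greedy cuts 3 edges where the optimal coherent partition cuts 1.
  Similarly, adding an edge inside a returned cluster usually (≈ 97% of
  seeded trials) leaves the edge cut unchanged or smaller, but can
  occasionally redirect early greedy choices and enlarge it. These are
  properties of the published procedure, reproduced faithfully, not
  implementation artifacts.
* Overlapping complexes and weighted or directed networks are out of
  scope: the output is a hard partition of an unweighted undirected
  simple graph.
* GO-based functional evaluations (semantic similarity, enrichment) are
  not included; they require external ontology and annotation resources.
* The evaluation suite intersects gold standards with the network only on
  request (`restrict_gold = TRUE`); by default absent proteins depress
  recall-type measures, which is the conservative reading.
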