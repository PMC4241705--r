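---
title: "Local PPI network alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local PPI network alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinalign)
```

## The problem

A protein–protein interaction (PPI) network is an undirected graph whose
nodes are proteins and whose edges carry the probability that the two
proteins physically interact. Given two such networks $G_1 = (V_1, E_1)$
and $G_2 = (V_2, E_2)$ and a table of cross-species sequence similarities
(BLAST bit scores), *local network alignment* looks for pairs of subgraphs
— one from each network — together with a vertex mapping between them, such
that mapped proteins are similar in sequence and their interactions are
conserved. Local alignments are partial by nature: most proteins are not
mapped at all, and a protein may legitimately correspond to two proteins in
the other species when a gene duplication occurred after the species
diverged.

`pinalign` implements a complete local aligner around a beam-pruned
dynamic-programming core, plus the ortholog-group (KO) based
specificity/sensitivity metrics used to evaluate such aligners, and a
synthetic network-pair generator with planted orthology so every stage can
be validated without external database downloads.

A *local alignment* is a triple $(S_{g1}, S_{g2}, M)$: a subgraph of $G_1$,
a subgraph of $G_2$, and an injective mapping $M$ of the first onto the
second. An edge $(u, v) \in E_1$ is *conserved* under $M$ if
$(M(u), M(v)) \in E_2$.

## Stage 1: hub clustering

PPI networks are sparse but contain dense regions organised around
high-degree *hubs* (protein complexes live there, and so do conserved
modules). The first network is therefore partitioned into hub-centred
clusters and each cluster is aligned independently:

1. **Hub selection.** Hubs are the nodes whose degree strictly exceeds the
   empirical `hub_percentile` quantile of the degree multiset (default
   0.95). The quantile is the nearest-rank value — the element at rank
   $\lceil p\,|V|\rceil$ of the ascending degree list — which makes the
   rule fully reproducible; ties at the threshold are excluded. If no node
   exceeds the threshold (degree-regular graphs), the single top-degree
   node is used and a message is emitted.
2. **Assignment.** Every edge gets length $-\ln p$, so high-confidence
   interactions are short, and a multi-source Dijkstra run assigns each
   node to its nearest hub. The natural logarithm is a convention only: any
   base induces the same shortest paths. A probability of exactly 1 gives a
   legitimate zero-length edge; probability 0 is rejected outright
   ($-\ln 0$ is infinite, and an absent interaction is simply an absent
   edge). Distance ties go to the earlier hub in (degree-descending,
   ID-ascending) order; hubs always own themselves; nodes unreachable from
   every hub are reported and excluded from alignment, since a hubless
   fragment has no defined cluster.

Only the first network is clustered — the method is intentionally
asymmetric in its two inputs (the CLI exposes `--swap` to exchange roles).

## Stage 2: the candidate engine

Within one cluster the aligner grows *candidates* — local alignments — by
dynamic programming over *candidate collections*, the sets of retained
candidates sharing one $G_1$ vertex set:

* **Seeds.** Every cluster vertex $v$ with at least one positively scored
  partner $u$ yields a size-1 collection holding one candidate $v \mapsto u$
  per partner. Vertices without scored partners are skipped (logged).
* **Merge order.** Collections are merged pairwise following a hierarchical
  agglomeration over the connectivity distance
  $$d(V_i, V_j) \;=\; \frac{|V_i| + |V_j|}
      {\sum_{v \in V_i}\sum_{u \in V_j} a_{v,u}/e_{v,u}},$$
  where $a_{v,u}$ indicates an edge between the two sets and
  $e_{v,u} = -\ln P_{G_1}(v,u)$ is its length. Densely interconnected,
  high-confidence sets merge first, which is what lets merged candidates
  accumulate conserved edges early. Distances are recomputed exactly on the
  union sets at every step (the distance is defined on arbitrary subgraphs;
  at the scale of one cluster, exactness is affordable and avoids linkage
  approximations). No connecting edge gives distance $\infty$ — such pairs
  merge last, under the same deterministic smallest-member-ID tie-break, so
  the merge tree always completes. A probability-1 connecting edge gives
  distance 0.
* **Merging.** Merging two collections forms the union candidate of every
  pair of member candidates whose $G_2$ images are disjoint; pairings that
  would reuse a $G_2$ vertex are skipped, keeping every candidate an
  injective mapping. (One-to-two relationships are deliberately *not*
  handled here — duplication is resolved later, in the matching stage.) If
  every pairing conflicts, the higher-scoring parent collection is adopted
  unchanged, so one poisoned pair cannot erase a whole subtree; the
  adoption is logged.
* **Scoring and pruning.** Candidates are ranked by two objectives in
  lexicographic order. The *node score*
  $$NS(C) = \sum_{v \in S_{g1}} \mathrm{bit}(v, M(v))$$
  is the total sequence similarity of the mapping and is exactly additive
  under merges. The *structural score*
  $$SS(C) = \sum_{v \neq u \in S_{g1}}
      \bigl(f(v)\,f(u)\bigr)^{\alpha}
      \bigl(P_{G_1}(v,u)\,P_{G_2}(M(v),M(u))\bigr)^{1-\alpha}$$
  runs over ordered vertex pairs whose edge is conserved (all other terms
  are 0) and rewards *bridges*: $f(v)$ counts conserved edges at $v$, so
  pairs of vertices that anchor many conserved interactions dominate. The
  exponent $\alpha \in [0,1]$ (default 0.5, exposed as configuration)
  balances this degree structure against the joint interaction
  probability; $0^0$ is taken as 1 so both endpoints $\alpha = 0$ (pure
  probability) and $\alpha = 1$ (pure degree) degenerate cleanly. The sum
  over ordered rather than unordered pairs doubles every score and is
  ranking-irrelevant. After every merge only the best `beam_width`
  candidates are kept (default 100 — collection cardinality would otherwise
  grow exponentially along the tree; 100 keeps the full pipeline
  interactive at validation scale while leaving pruning observable). All
  sorts carry a final deterministic tie-break on the printed form of the
  mapping.

Because the node score is the primary sort key and is additive, the
implementation first ranks merged pairs by node score alone and evaluates
the (more expensive) structural score only for the candidates that can
still reach the beam — an optimisation that provably does not change the
result, and is cross-checked against exhaustive enumeration in the test
suite.

One structural consequence of the merge semantics is worth knowing: the
engine always unions both parents' vertex sets when *any* compatible
pairing exists. It can therefore never decide to leave a seeded vertex
unaligned, even when that vertex's only partners clash with the otherwise
best assignment and including it lowers the total node score. The
exhaustive-search comparison in the acceptance tests measures exactly this
gap on small random instances.

## Stage 3: similarity bipartite graph and matching

The per-cluster *final candidate collections* are combined into a single
alignment through a weighted bipartite graph over $V_1 \times V_2$:

* **Support.** $C(v, u)$ is the set of final candidates mapping $v$ to
  $u$; pairs no candidate supports get no edge.
* **Edge weight.**
  $$W(v, u) \;=\; \mathrm{bit}(v,u)\,\lvert C(v,u)\rvert
      \;+\; \frac{1}{\lvert C(v,u)\rvert}
            \sum_{c \in C(v,u)} \sum_{\substack{v' \in N_{G_1}(v) \\ v' \in c}}
            \mathrm{bit}\bigl(v', M_c(v')\bigr).$$
  The first term amplifies the sequence similarity by the number of
  candidates agreeing on the pair — consensus across independently grown
  candidates is strong evidence of orthology, and this amplification is
  what separates true pairs from incidental low-score hits. The second term
  is the mean, per supporting candidate, of the similarity of $v$'s
  conserved neighbourhood.
* **Degree-3 reduction.** Extracting matches and one-to-two matches
  (*DMatches*, length-2 paths modelling duplication) directly from this
  graph is expensive, so it is first thinned: duplicate every left vertex
  (the duplicate carrying identical edges), take a maximum-weight bipartite
  matching, and merge duplicates back, giving a subgraph $M_1$ with left
  degrees $\le 2$ and right degrees $\le 1$; repeat symmetrically for the
  right side ($M_2$); keep the union. Every vertex of the result has degree
  at most 3 — this bound is guaranteed by construction and asserted on
  every run. The matching itself is delegated to igraph's exact
  weighted bipartite matching (the Hungarian-equivalent step), fed with
  sorted vertex and edge orders so results are reproducible. **Limitation:**
  the reduction does *not* always preserve the optimal total DMatching
  weight. $M_1$ can only host solutions whose one-to-two matches are all
  centred on the left, $M_2$ only right-centred ones, and an optimal
  solution mixing both orientations may need edges that are strictly
  dominated in *both* matchings and hence absent from the union. The test
  suite compares the reduced graph's exhaustive optimum against the full
  graph's on small random instances and documents the discrepancy rather
  than hiding it.
* **Greedy extraction.** On the reduced graph: edges whose two endpoints
  both have degree 1 become matches immediately; every degree-2 vertex
  proposes one DMatch and every degree-3 vertex three (one per partner
  pair); proposals are sorted by weight (ties: centre ID, then partner IDs)
  and accepted greedily, deleting all edges incident to the three consumed
  vertices; finally, surviving single edges are matched one-to-one in
  descending weight order so no recoverable weight is left on the table.
  That last clean-up step, and the rule that a vertex consumed by an
  accepted DMatch can never reappear in a later match, are this package's
  design choices where the procedure leaves room; both are deterministic.
  The greedy total never exceeds the exhaustive DMatching optimum, which
  the tests verify on small instances.

## Evaluation metrics

The aligned-to relation is made transitive (a DMatch links its centre to
both partners) and its connected components become *equivalence classes*,
tracked per network so identical identifiers in the two species stay
distinct. Against a protein-to-ortholog-group mapping, a class is *correct*
iff every member is annotated and all annotations agree. Four measures
follow: `c_eq`, the fraction of correct classes, and `c_node`, the fraction
of member proteins in correct classes (specificity); `c_or`, the number of
proteins in correct classes, and `tot`, the number of classes containing
both species (sensitivity). Requiring annotation is a design choice — a
class containing an unannotated protein cannot be verified; passing
`exclude_unannotated = TRUE` instead drops such classes from the
denominators, and `tot` is always counted before exclusion.

## The synthetic generator

`generate_pair()` emulates the input regime the aligner is designed for:

* **Topology.** The first network grows by preferential attachment (two
  edges per new node) from a fully connected core of
  $\max(2, \lceil \mathrm{hub\_fraction} \cdot n \rceil)$ nodes (default
  fraction 0.05). Preferential attachment — rather than an Erdős–Rényi
  draw — guarantees the heavy-tailed degree distribution with genuine hubs
  that hub clustering presumes; the seed core makes small instances behave
  like the dense regions of larger networks. Edge probabilities are uniform
  on $[0.5, 1]$, the upper half of the confidence scale.
* **The second network** is a relabelled copy with each edge kept
  independently with probability `edge_keep` and probabilities jittered by
  $\pm 0.1$ (clamped to $(0,1]$), emulating incomplete and noisy
  interactome coverage.
* **Scores.** Planted ortholog pairs draw bit scores from $[50, 200]$;
  every non-orthologous cross pair independently receives a score from
  $[1, 40]$ with probability `score_noise_rate`. The bands are disjoint on
  purpose: recovery experiments then probe the aligner's use of network
  structure and consensus, not the generator's score overlap.
* **Annotation truth.** Each planted pair gets its own ortholog group, so
  the evaluation metrics have an exact ground truth.

All randomness derives from the single `seed` argument; identical arguments
give byte-identical serialisations. `self_alignment_fixture(n, seed)` is
the `edge_keep = 1`, 5%-noise special case in which the planted mapping is
the unambiguous optimum.

What the generator does **not** emulate: realistic BLAST score
distributions (real bit scores correlate with protein length and family
structure, and true orthologs can score weakly), many-to-many homology
families, correlated false-positive interactions, or networks at
interactome scale. Passing the planted-recovery tests therefore shows the
pipeline is a faithful, deterministic implementation that exploits
consensus and conserved structure — not that it would reach the same
numbers on real interactomes.

## Validation scale and numerical choices

The exhaustive oracles that anchor the test suite (permutation matching,
enumerated DMatchings, full local-alignment search) are only tractable on
small instances, so the suite runs them on networks of up to 6 nodes,
clusters of up to 5, bipartite graphs of up to 5+5, and full-pipeline
fixtures of 60 proteins over multiple generator seeds — sizes chosen so
that every comparison against brute force is exact while the whole suite
stays interactive. Determinism is treated as a contract: every sort in the
pipeline carries a total tie-break, no stage consumes hash-order
iteration, and two runs on identical inputs produce byte-identical output
files.

Degenerate inputs are defined, not accidental: an empty score table yields
an empty alignment; a cluster with no scored vertex yields an empty
collection; an empty alignment evaluates to all-zero metrics (logged);
duplicate network rows collapse to the maximum probability; self-loops are
dropped with a warning.

## Known limitations

* Only the first network is clustered; results are not symmetric in the
  two inputs. Use `--swap` (CLI) or exchange the arguments to flip roles.
* Scoring uses dense probability matrices internally — appropriate for the
  desk-scale networks the exhaustive validation targets, not for
  interactome-scale inputs.
* The greedy DMatch extraction and the degree-3 reduction are heuristics;
  the candidate engine cannot leave a seeded vertex unaligned. All three
  gaps are measured against exhaustive search in the tests instead of
  being assumed away.
* The input weight scale is taken at face value as interaction
  probabilities in $(0, 1]$; no rescaling of upstream confidence scores is
  attempted.
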