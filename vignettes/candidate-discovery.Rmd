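---
title: "Dense-subgraph mining of PPI networks for assembly-factor discovery"
author: "ppidiscover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense-subgraph mining of PPI networks for assembly-factor discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidiscover)
```

## The problem

Respiratory-chain complexes such as the yeast ubiquinol–cytochrome *c*
reductase (complex III) are assembled with the help of dedicated assembly
factors, most of which are still unknown; classical respiratory-deficiency
screens miss factors that are essential for viability.  `ppidiscover`
implements an *in silico* route to candidate factors: build a
seed-centred physical-interaction network around the known subunits of a
complex, partition it into highly interconnected sub-graphs, and look at
what is *left over* — proteins of a parent cluster that no dense
sub-cluster captures, yet that are tied to a few "anchor" subunits of the
complex.  Those residual, anchor-connected proteins are the candidates.

## The network model

The network is an un-weighted, undirected simple graph over standard gene
names, with self-interactions (homodimers) kept as loop edges.  Each
physical interaction counts once regardless of how many experiments
observed it: weighting by observation count would systematically favour
the most-studied proteins, so evidence multiplicity is recorded as
metadata only.  Genetic interactions are excluded at parse time — genetic
screens cover genes very unevenly and would unbalance the network.

Assembly follows five steps: (1) the *level-1.5 neighborhood* of the
seed list in the first source (all interactions touching a seed, plus all
interactions between two proteins that each interact with a seed) gives
list 1, and the direct interactions of the seeds in the second source
give list 2; (2) identifiers are unified to standard gene names before
merging; (3) for proteins present only in the second source, their
interactions with non-seed proteins of list 1 are added as list 3;
(4) the lists are merged with redundancy eliminated; (5) the result is an
un-weighted network.  Step 3 is worded ambiguously in the underlying
method description; here the join targets are the list-1 endpoint
proteins *excluding* the seeds (direct seed edges are already in list 2),
and interactions among the new proteins themselves are not added.  Both
choices keep list 3 focused on the functional environment of the new
proteins; a broader join is easy to emulate by re-running
`expansion_delta()` with a different target set.

## Overlapping clustering by cohesiveness growth

A cluster's *cohesiveness* (quality) is `m_in / (m_in + m_bound)`, the
internal edges over all edges touching the cluster; its *density* is
`m_in / (n(n+1)/2)`, internal edges over all theoretically possible pairs
*with repetition*, because self-interactions are permitted.  A self-loop
contributes one internal edge and one unit of intra-degree, never a
boundary edge; this single-count convention keeps quality in [0, 1].

`grow_from_seed()` starts from a single node and repeatedly applies the
best strictly improving single move — adding an external boundary node or
removing a current member — until no move improves cohesiveness, i.e. a
local maximum.  Numerical choices worth knowing:

* Quality comparisons are exact: candidate qualities are compared by
  cross-multiplying the integer edge counts, so floating-point rounding
  can never order two moves inconsistently between runs.
* Ties are broken deterministically (additions before removals, then the
  lexicographically smallest node), seeds are processed in decreasing
  degree order with lexicographic tie-break, and nodes already covered by
  an accepted cluster are not re-seeded.  Re-running on the same network
  is byte-identical.
* An isolated seed returns a singleton with quality 1 (the empty ratio is
  defined as 1).

`cluster_one()` then discards clusters smaller than `min_size` (3),
sparser than `min_density` (0.25), or with a one-sided Mann–Whitney
p-value above `max_pvalue` (0.05), and iteratively merges accepted
clusters whose *match coefficient* `|A∩B|²/(|A||B|)` reaches
`overlap_threshold` (0.8).  The defaults are the pipeline's published
operating point: a density floor of 0.25 yields several overlapping
sub-graphs of good quality.  The merge metric itself is the convention of
the published overlapping-clustering tool, since only the threshold is
stated in the method description.  Merged clusters are re-scored but not
re-filtered (merging happens after discarding).  The quality function is
deliberately the plain two-term ratio; the published variant's per-node
penalty is available as `node_penalty` (default 0).

The cluster p-value compares, across member nodes, the intra-degree
against the boundary-degree with a one-sided Mann–Whitney U test (the
alternative: intra-degrees are stochastically larger).  For samples of up
to 10 values each the p-value is computed by exact enumeration of the U
distribution — a dynamic program over doubled midranks, which handles
ties exactly, something the asymptotic test only approximates.  Larger
clusters use the tie-corrected normal approximation with continuity
correction.  A singleton has no defined test and returns p = 1 with a
warning.

## Disjoint clustering by vertex weighting

When a cluster cannot be split into overlapping sub-graphs any further,
it is split into *independent* sub-graphs.  Every node is weighted by its
local neighborhood density: with H the subgraph induced by the node's
closed neighborhood and k* the highest core order in H, the weight is k*
times the density of the highest k-core of H (self-pairs excluded; nodes
whose neighborhood holds no core of order `min_core` = 2 weigh 0).
Complexes grow breadth-first from unassigned seeds in decreasing weight
order, admitting unassigned neighbors whose weight is at least
`(1 − vwp)` times the seed weight (`vwp` = 0.2), to a depth limit of 100.
A node assigned once is never re-used, so complexes are node-disjoint.
The haircut step (on by default) iteratively removes members with fewer
than two within-complex neighbors; fluff is off by default; complexes
below 3 nodes are suppressed for consistency with the pipeline-wide
minimum size.  These are the published defaults of the
molecular-complex-detection algorithm, the only defensible reading of
"default parameters".  Self-loops are ignored throughout this module:
they carry no neighborhood-density information.

Note one consequence of threshold expansion: in a graph whose nodes all
tie in weight (e.g. two equal cliques joined by one edge) the expansion
crosses the bridge and returns a single complex.  Splitting requires an
actual weight contrast between the regions.

## Recursive partitioning and subtraction

`partition_recursive()` applies the overlapping clustering to the current
induced subgraph and recurses into the *seed-richest* accepted cluster
(ties: higher quality, then smaller size).  A branch is declared
unsplittable — and handed to the disjoint algorithm exactly once — when
the overlapping step accepts nothing, or accepts a single cluster
covering ≥ 95% of the input, or accepts no seed-containing cluster, or
when `max_depth` (5) is reached.  The 95% coverage operationalizes
"cannot be split further", which the underlying method leaves
unquantified.  The disjoint step runs on the induced subgraph of the
node it splits, not on the whole network restricted afterwards.

`subtract_residual()` is the literal set difference between the split
node and the union of its disjoint children.  `anchor_candidates()` keeps
residual proteins with at least one edge to an anchor subunit and ranks
by anchor edges, then seed edges, then name; residual proteins that are
themselves seeds are annotated and ranked last.  The ranking formula is a
package convention: the decisive triage of real candidates (annotation
status, essentiality, localization) is biological and out of scope, so it
surfaces only as an annotation column.  By default the anchors are the
seed proteins sitting in the highest-scoring disjoint child that contains
seeds — the subunits that clustered away from their own complex — and can
be overridden with `anchors =`.

## The synthetic benchmark

`planted_network()` draws modules as Bernoulli(`intra_p`) subgraphs,
cross-module pairs at `inter_p`, background-involving pairs at
`background_p`, and attaches each satellite to `satellite_degree`
distinct anchors *and nowhere else* — low, anchor-focused connectivity is
the defining property of the residual candidates the subtraction step is
built to find.  Everything is reproducible from `rng_seed` alone.
`discovery_scenario()` fixes the shape to module A (17 nodes, 2 anchors),
module B (8 nodes), `intra_p` 0.85, A–B cross rate 0.15, 5 satellites
with 2 anchor edges, 60 background nodes at 0.02, and a 10-protein seed
list (module B plus the anchors), emulating a complex whose subunits
split across two dense sub-clusters.  Edge probabilities are stated
parameters, not fits to any real interactome; the generator reproduces
the *topology class* of the discovery problem, not degree distributions,
evidence biases, or study-frequency effects of real snapshot data, so
green tests here certify algorithmic behavior, not performance on real
databases.

## Known limitations

Two behaviors of strictly improving cohesiveness growth matter in
practice, and both are visible in the test suite:

* **Union cascade.** When two dense modules share nodes and the graph has
  little surrounding structure, their union has no boundary and hence
  quality 1.  A single cross-module node with `a` edges into the grown
  cluster and `b` outside joins whenever `a > q·b`; once one slips in,
  the rest follow.  At `intra_p` 0.9 / `inter_p` 0.05 with two size-10
  modules sharing 2 nodes this collapses roughly one replicate in five
  to the union instead of the two modules (the suite measures the exact
  rate), under the plain and the penalized quality function alike.
* **Pendant absorption.** Adding a degree-1 neighbor always improves
  cohesiveness, so in sparse surroundings a growing cluster accretes
  low-degree appendages, diluting density until the 0.25 filter rejects
  it.  On the fixed benchmark scenario this suppresses the
  seed-containing clusters at the whole-network level, the partition
  falls through to the disjoint split early, and background nodes that
  happen to touch an anchor contaminate the candidate list; the
  planted satellites are all recovered, but not alone.

Both are properties of the growth procedure itself, not of its
implementation; the corresponding end-to-end expectations in the test
suite are intentionally strict and document where the procedure's
guarantees end.  Practical analyses should treat the candidate list as a
ranked shortlist for manual triage — exactly how it is used downstream —
rather than as an exact recovery.

## Problem sizes used in the checks

The suite exercises exhaustive oracles on graphs of up to 10 nodes
(edge-classification, exact U-test enumeration, independent disjoint
detection), local-maximality on fifty 40-node random graphs, module
recovery on fifty 18-node planted replicates, and the fixed 90-node
benchmark scenario end to end; these sizes keep every oracle exact or
exhaustively checkable while covering all code paths.
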