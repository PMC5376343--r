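---
title: "Reconstructing kinase signaling networks and ranking propagation paths"
author: "SigNetPath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing kinase signaling networks and ranking propagation paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigNetPath)
```

# The problem

Differential phosphoproteomic experiments around a kinase — inhibiting it
in cells that express it, or expressing it in cells that lack it — produce
lists of direct and indirect targets, but no account of how the signal
travels from the kinase to each target. Pathway databases contain the
needed interactions, yet a merged pathway network is far too dense to read:
a typical source-to-target query admits thousands of routes. `SigNetPath`
implements a pruning strategy that combines three ingredients, each
compensating a weakness of the others:

* **shortest paths** minimize the number of steps but ignore biology and
  return too many ties;
* **evidence-based edge distances** encode what the datasets and Gene
  Ontology say about each interaction, at the cost of hand-set levels;
* **a random walk with return probability** propagates information along
  the whole network and smooths incidental weight differences, but by
  itself ranks nodes, not paths.

The package's pipeline runs them in sequence: curate targets, select
over-represented pathways, merge and annotate, assign distances, refine
them with the walk's stationary distribution, and finally extract all
near-shortest source-to-target routes with a per-element overflow
annotation.

# Target curation

Three evidence classes are curated, and kept distinct because the distance
scheme treats them differently:

* **complex-level** (`selectRatioTargets`): proteins whose SILAC ratio
  departs from 1 by at least the `threshold` fraction (default 0.1,
  dimensionless). The bound is inclusive — a ratio of exactly 1.10 or 0.90
  reflects a 10 % variation and is kept (a 1e-12 guard absorbs binary
  representation error at the boundary). The raw ratio is filtered, not
  its logarithm, so up- and down-regulation bands are asymmetric on a log
  scale; this follows the rule as a laboratory would state it.
* **site-level** (`selectExclusivePeptides`, `mapPeptidesToProteins`):
  phosphopeptides observed in exactly one condition. The peptide key is
  (sequence, phosphosite) with the oxidation state deliberately left out
  of the key, so peptide pairs differing only by methionine oxidation
  collapse onto one key and are excluded as non-differential. Peptides
  matching several proteins through sequence redundancy contribute every
  match; proteins with exclusive peptides on both sides become
  direction `"mixed"` but remain targets.
* **direct substrates** (`selectDirectSubstrates`): in-vitro kinase-assay
  peptides that recur among the cellular condition-exclusive positive
  peptides. The hand-curated corrections (proteins to drop, one peptide to
  drop while keeping its protein, substrates to force in) ship as a YAML
  file (`curationDefaults()`) rather than hard-coded logic, so the
  mechanism transfers to other kinases.

# Enrichment and assembly

`fisherEnrichment` tests each pathway's 2×2 table with the two-sided
Fisher exact test, then applies the over-representation filter
k/m ≥ n/N separately; the two-step form keeps the test symmetric while
discarding depletion, and a one-sided `"greater"` mode is available. No
multiple-testing correction enters the selection — the cutoff
`alpha = 0.1` on the raw p-value is deliberately permissive because this
step aims at coverage, not inference — but a Benjamini–Hochberg column is
reported for transparency. The background defaults to all proteins of the
database's pathways; any explicit background can be supplied, since the
right choice (database universe versus detected proteome) is a judgement
call. After selection, `rescuePathways` restores, for every target
contained in the database but in no selected pathway, its best containing
pathway (smallest p, ties to the smallest pathway then lexicographic id;
an `"all-containing"` policy is available).

`mergePathways` produces one node per canonical id and one edge per
ordered pair. Canonicalization strips isoform suffixes and maps KEGG/HGNC
ids through a Uniprot id-mapping table; accessions sharing a foreign id
are grouped under one representative, preferring reviewed entries and
breaking ties lexicographically; groups connected through different
namespaces are union-merged. Interaction types union across pathways and
signs join on the lattice positive/negative → unclear with unknown
neutral. KGML multi-gene entries and explicit group entries become group
nodes whose member links are marked edges, so the pre-explosion network
remains exportable; `explodeGroups` flattens nested groups to protein
level before any path computation. GO annotation closure follows `is_a`
edges of a go-basic ontology (optionally `part_of`), unfiltered by
evidence code by default, with both choices configurable.

# Distances, the walk, and refinement

The six distance levels are dimensionless costs; smaller is more
plausible. Rule precedence matters and is fixed: the promotion branch for
modifier sources (d = 2, d = 1) is evaluated before the demotion branch
(d = 8, d = 6) because demotion concerns only edges that do *not* leave a
tyrosine kinase or phosphatase. "Identified" means any dataset evidence;
"differentially phosphorylated" means site-level or direct-substrate
evidence — the mapping is part of the scheme configuration
(`distanceScheme()`).

The walk's transition probabilities invert the distances,
$p_{ij} = (1-p_0)\,d_{ij}^{-1} / \sum_{k \in \mathrm{Succ}(i)} d_{ik}^{-1}$,
with a uniform return probability $p_0$ to the source added to every row
and terminal rows returning with probability 1. The return edge makes the
chain on the source-reachable component ergodic, so the stationary
distribution $\pi$ ($\pi P = \pi$) exists, is unique and strictly
positive there; the walk is therefore restricted to that component, which
is also the only region where source-to-target paths live. The default
$p_0 = 0.15$ is the conventional restart value for network propagation;
results are used as rankings and are insensitive to moderate changes.
The equal-weight run $\pi^0$ removes pure topology (hubs score high under
any weighting), and refinement multiplies each edge by its source's
$\pi^0_i/\pi_i$: nodes visited above topological expectation see their
outgoing edges promoted. Since the factor is per-source-node, refinement
rescales whole out-neighborhoods and so reranks *paths* through
over-visited nodes. When all base distances are equal the two chains
coincide and refinement is exactly neutral. Nodes with $\pi_i = 0$ cannot
occur inside the component, but edges leaving it (possible when a custom
score vector is supplied) receive the largest observed $\pi^0/\pi$ factor
— maximally demoted but finite, keeping the graph connected for search.

The stationary solver is deterministic power iteration (tolerance 1e-10 on
the L1 residual, at most 1e5 iterations, error on non-convergence); a
seeded trajectory sampler exists only as a cross-check in the tests.

# Near-shortest extraction and overflow

For targets $t$ and allowed overflow fraction $\varepsilon$ (default 0.2),
an edge $(u,v)$ is retained iff
$d_{\mathrm{fwd}}(u) + d(u,v) + d_{\mathrm{bwd},t}(v) \le
(1+\varepsilon)\, d_{\mathrm{fwd}}(t)$ for some $t$; nodes are retained
when incident to a retained edge. The implementation runs one forward
Dijkstra from the source and one backward Dijkstra per target (restricted
to the source-reachable component), rather than literal backtracking,
because the inequality yields each element's overflow directly: the
minimum, over served targets, of the best acceptable route length through
the element minus the target's shortest distance. Shortest-path elements
have overflow exactly 0, all tied optimal routes are kept, and a node's
overflow is the minimum over its retained incident edges. Two properties
follow from the construction and are enforced by the test suite:
subnetworks grow monotonically with $\varepsilon$, and every retained
element lies on at least one acceptable route. The *composite* subnetwork
can contain walks longer than acceptable (two individually acceptable
detours may share a middle node); this is a documented feature of the
union representation, not an error. On cyclic graphs "route" means a walk:
the acceptance inequality is equivalent to the existence of an acceptable
source-to-target walk through the element, which is exactly what
backtracking over Dijkstra distances admits; requiring simple paths
instead would make retention NP-hard and exclude elements the backtracking
construction keeps. The overflow threshold is relative, matching the
"up to 20 % longer" reading; an absolute slack mode exists for calibrated
distance scales. Floating-point ties are absorbed by a 1e-9 relative
guard, and overflows within that guard of zero are clamped to exactly 0.

# What the fixture generator emulates

`generateFixture` writes a complete input bundle — KGML with a group
construct, extended SIF, GMT, GAF, a stub go-basic OBO, a Uniprot
id-mapping table with grouped unreviewed accessions, and the two proteomic
tables — with planted ground truth: one or more source → kinase → target
chains whose nodes carry the annotations that give their edges distance 1.
Defaults (60 proteins, 6 pathways of 8–15 members, 80 noise edges, 15 %
of proteins carrying dataset evidence, 5 shared peptides plus 2
oxidation-only pairs) are sized so that a planted pathway is clearly
enriched at p < 0.1 while noise pathways are not, and so the full pipeline
runs in well under a second per seed; they were chosen once, as plausible
miniatures of a curated study, and the suite runs 20 seeds end to end.
Noise edges are Erdős–Rényi within pathways, never leave a
phospho-tyrosine modifier (curated kinase edges are exactly the planted
ones), and are resampled until no route undercuts a planted path — the
generator certifies its own ground truth. What the fixtures do *not*
emulate: scale-free interactome topology, correlated pathway membership,
peptide-level noise such as missed cleavages, and realistic GO depth.
Passing tests therefore demonstrate algorithmic correctness on known
ground truth, not biological performance on real databases.

# Degenerate inputs and numerical edge cases

Non-positive SILAC ratios and malformed phosphosites are rejected row-wise
with warnings; unknown identifiers are kept, flagged, and reported rather
than dropped. Empty groups, absent source nodes, empty backgrounds, p₀
outside (0,1) and non-positive distances are hard errors. When no
requested target is reachable the extraction returns an empty subnetwork
with a warning. A source that is its own only target yields the degenerate
single-node subnetwork.

# Limitations

Signs are reconciled but not used by the search (a positively and a
negatively signed route of equal length rank equally); distances are
hand-set levels, not learned; k-shortest-path enumeration and Steiner-tree
extraction are out of scope, as is any hosted visualization — exports are
GraphML/SIF for Cytoscape and JSON for lightweight viewers. Reproducing a
published network requires the same database releases; the package
guarantees the algorithms, not the snapshot.
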