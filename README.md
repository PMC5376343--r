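# SigNetPath

Reconstruction and signal-propagation analysis of kinase signaling
networks from (phospho-)proteomic target lists.

Quantitative phosphoproteomics yields lists of proteins whose
phosphorylation state depends on a kinase of interest — for example the
spleen tyrosine kinase Syk (Uniprot P43405) in breast cancer cells — but
not the intermediary pathways through which the signal reaches them.
`SigNetPath` closes that gap: starting from curated target lists it builds
an annotated directed interaction network from over-represented pathways
and extracts ranked, near-shortest candidate routes from the source kinase
to each target. It is written for computational biologists who have
differential proteomic datasets in hand and want mechanistic hypotheses
they can test at the bench.

## The method

1. **Target curation.** Complex-level targets are proteins whose SILAC
   ratio *r* shows at least a 10 % variation (|r − 1| ≥ 0.1). Site-level
   targets come from phosphopeptides observed exclusively in one condition
   (peptides seen in both conditions are discarded, collapsing pairs that
   differ only by methionine oxidation); ambiguous peptides contribute all
   matching proteins. Direct substrates are in-vitro kinase-assay targets
   whose phosphopeptide recurs among the cellular condition-exclusive
   peptides, subject to a shipped curation list.
2. **Pathway enrichment.** Each pathway containing a target is tested with
   the Fisher exact test on the 2×2 table (in-pathway × target) against a
   background set; under-represented pathways (k/m < n/N) are removed, the
   rest kept when p < 0.1, and pathways containing otherwise-uncovered
   targets are rescued.
3. **Network assembly.** Selected KGML / extended-SIF pathways are merged
   into one directed network: one node per canonical Uniprot id (isoform
   suffixes stripped; KEGG and HGNC ids mapped, grouped accessions
   represented by a reviewed entry), one edge per ordered pair with types
   unioned and signs reconciled (positive + negative → unclear). Nodes are
   tagged with GO-derived process categories, phospho-tyrosine-modifier
   status (GO:0004713/GO:0004725 plus manual overrides) and dataset
   evidence; group nodes are exploded to protein level before path search.
4. **Edge distances.** Each edge i→j gets a distance d<sub>ij</sub> from
   its endpoints' annotations: d = 5 for a plain edge, 3 out of an
   identified protein, 2 from a tyrosine kinase/phosphatase into an
   identified protein, 1 when both hold; edges into a differentially
   phosphorylated target that do *not* leave a modifier are demoted to 8,
   or 6 when the source is at least identified.
5. **Random-walk refinement.** A Markov chain with transition
   probabilities p<sub>ij</sub> = (1 − p₀) · d<sub>ij</sub>⁻¹ / Σ<sub>k∈Succ(i)</sub> d<sub>ik</sub>⁻¹
   and uniform return probability p₀ to the source (terminal nodes return
   with probability 1) is solved for its stationary distribution π
   (πP = π, by power iteration). A second, equal-weight run gives the
   topology baseline π⁰, and distances are refined as
   d̃<sub>ij</sub> = d<sub>ij</sub> · π⁰<sub>i</sub>/π<sub>i</sub>, promoting
   edges out of nodes visited above their topological expectation.
6. **Near-shortest extraction.** An edge (u,v) is kept iff, for some
   target t, d<sub>fwd</sub>(u) + d(u,v) + d<sub>bwd,t</sub>(v) ≤ (1 + ε)·d<sub>fwd</sub>(t)
   with ε = 0.2 by default; every retained element is annotated with its
   *overflow*, the extra distance of the best acceptable route using it
   (0 on shortest paths).

## Worked example

Every stage runs offline on a synthetic fixture bundle with planted ground
truth (a source kinase S = `P00001`, a planted route through the kinase
`P00002` to the target `P00003`, plus noise pathways and edges):

```r
library(SigNetPath)
fx  <- generateFixture(fixtureSpec(seed = 1), "demo")
gt  <- fx$groundTruth
cfg <- runConfig("demo", "demo/out")

targets <- cmdTargets(cfg)
targets$merged
#> TargetSet: 17 proteins, 18 member records
#>   tags: complex-level=6, direct-substrate=3, site-level=9

build <- cmdBuild(cfg, sourceId = gt$source, targets = targets)
#> network: 9 nodes, 16 edges from 1 pathways; 7/17 targets covered, 7 reachable

res <- cmdExtract(cfg, build, mode = "refined",
                  targets = gt$plantedTargets)
edgeTable(res$subnetwork)
#>   source target overflow
#> 1 P00001 P00002        0
#> 2 P00002 P00003        0
```

The extraction recovers exactly the planted route `P00001 → P00002 →
P00003` with overflow 0: both edges lie on a strict shortest path under
the refined distances. The walk scores show why — the planted kinase is
visited above its topology baseline:

```r
head(walkScores(res$scores)[order(-res$scores@pi), ], 4)
#>       id        pi       pi0     ratio
#> 2 P00002 0.2494647 0.2454572 1.0163264
#> 1 P00001 0.2213906 0.1953283 1.1334279
#> 3 P00003 0.2210142 0.2208091 1.0009288
#> 5 P00037 0.1932853 0.1962284 0.9850017
```

`ratio > 1` marks nodes whose weighted-walk occupancy exceeds the
equal-weight expectation; their outgoing distances shrink under
refinement. GraphML/SIF files (openable in Cytoscape), enrichment and
path reports are written under `demo/out/`. A thin command-line wrapper
around the same functions is shipped at `inst/scripts/signetpath.R`
(subcommands `simulate`, `targets`, `build`, `extract`).

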