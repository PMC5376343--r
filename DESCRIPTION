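Package: SigNetPath
Title: Signaling Network Reconstruction and Near-Shortest Path Propagation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Reconstructs directed signaling networks from pathway databases
        seeded by (phospho-)proteomic target lists, and analyses signal
        propagation from a source kinase to its targets. Provides identifier
        canonicalization across Uniprot/KEGG/HGNC namespaces, curation of
        target sets from SILAC ratio and phosphopeptide tables, Fisher exact
        pathway over-representation with coverage rescue, pathway merging into
        an annotated directed network (interaction types, signs, GO process
        categories, phospho-tyrosine modifier flags, group-node explosion), an
        evidence-based six-level edge distance scheme, extraction of
        near-shortest source-to-target subnetworks with per-element overflow
        annotation, and a random-walk stationary-distribution refinement of
        edge distances. A synthetic fixture generator with planted ground
        truth supports fully offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, Matrix, xml2, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, fgsea, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: NetworkInference, Pathways, GraphAndNetwork, Proteomics,
        NetworkEnrichment
RoxygenNote: 7.3.3
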