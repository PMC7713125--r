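Package: halopan
Title: Pan-Genome Partitioning, Openness Curves and Ancestral Gene-Content
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pan-genome analysis for sets of prokaryotic proteomes,
    modelled on the workflow used for class Halobacteria: all-vs-all protein
    similarity with bidirectional-best-hit graphs and Markov clustering into
    gene families, genome quality filtering, core/softcore/shell/cloud
    occupancy partitioning with strict single-copy core extraction, Tettelin
    exponential pan- and core-size curve fitting with openness
    classification, Poisson-corrected distance core-gene trees
    (neighbor-joining plus minimum-evolution refinement and bootstrap) and
    presence/absence parsimony pan-genome trees, and Wagner/Sankoff parsimony
    reconstruction of ancestral gene content with per-branch gain/loss events
    and last-common-ancestor reports.  Includes a fully seeded synthetic
    pangenome generator (gene birth-death on a Yule tree with sequence
    evolution) so every stage can be validated against known ground truth,
    and an end-to-end pipeline driver with an evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Matrix,
    mclust,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
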