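Package: taxgen
Title: Gene-Content Phylogenomics and Species Delimitation for Bacterial Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome taxogenomic classification of bacterial strains from
    annotated proteomes. Detects reciprocal best-hit (bidirectional) gene pairs
    between genomes by local protein alignment, computes the gene-content
    distance d(G1,G2) = 1 - |G1 n G2| / min(|G1|,|G2|), builds neighbour-joining
    dendrograms, reports group core-genome fractions by residue length, and
    delimits species by the bimodal within/between identity regime. Includes a
    seeded pangenome simulator with a planted tree, planted core fractions and
    planted pairwise identities for ground-truth validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
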