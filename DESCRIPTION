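Package: lidasr
Title: Ancestral Reconstruction and Lid-Region Evolution of Fungal
    Versatile Lipases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens protein sets for Candida rugosa-like "versatile"
    lipases (signal peptide, GGG[FL]/G[EQ]SAG motifs, lid region, identity
    to an annotated reference), builds phylogenies under the WAG(+F)
    amino-acid model (neighbor joining topology, maximum-likelihood branch
    lengths, Felsenstein pruning), performs marginal ancestral sequence
    reconstruction at internal nodes, trims the hypervariable lid region of
    reconstructed ancestors by posterior-probability thresholds, and
    summarises lid length and hydrophobicity along the tree.  Includes a
    sequence-family simulator with known trees, ancestors and lid indels
    that serves as ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
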