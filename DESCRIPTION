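Package: orthopan
Title: Pan-Genome Inference with Phylogeny-Aware Cluster Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bacterial pan-genomes from annotated genomes: an
    all-against-all protein similarity graph is clustered with Markov
    Clustering (MCL), putatively orthologous clusters are refined by
    examining gene-tree structure (adaptive long-branch splitting, a
    per-branch paralogy score, and length-peak merging of unclustered
    fragments), gene gain and loss are inferred on the core-genome SNP
    tree under a two-state Markov model with maximum-likelihood rates,
    and numeric strain phenotypes are scored for association with gene
    presence/absence and with gene-tree branches.  A coalescent
    pan-genome simulator with gene gain, loss, transfer and HKY sequence
    evolution provides ground truth for benchmarking cluster accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    phangorn,
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
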