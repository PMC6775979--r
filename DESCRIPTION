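Package: featherbiome
Title: Feather Microbiota Diversity, Phylosymbiosis and Functional
    Fraction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for community analysis of avian feather microbiota
    from 16S rRNA OTU tables: rarefaction and alpha diversity,
    phylogeny-aware beta diversity (weighted and unweighted UniFrac,
    Bray-Curtis, binary Jaccard), unconstrained and constrained
    ordination (PCoA, NMDS, PERMANOVA, Mantel, distance-based RDA with
    PCNM spatial eigenfunctions, forward selection and adjusted-R2
    variance partitioning), Procrustean cophylogeny testing over a
    posterior sample of host trees, identity-threshold estimation of
    bacteriocin-producing and keratinolytic bacterial fractions, and a
    Bayesian phylogenetic mixed model with within-species centering
    fitted by a conjugate Gibbs sampler. A synthetic-study generator
    with known ground truth (species effects on a host phylogeny,
    spatially autocorrelated locality effects, trait-annotated
    sequence pools) supports power analysis and validation of the
    whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    phangorn,
    geosphere,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    jsonlite
Config/testthat/edition: 3
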