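Package: ychron
Title: Phylogeny Construction and TMRCA Estimation for the Male-Specific Y Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing haploid SNP and Y-STR variation on the
    male-specific region of the Y chromosome (MSY). Builds rooted
    mutation-annotated trees from polarized biallelic haplotypes by perfect
    phylogeny with parsimony placement of recurrent sites, estimates clade
    TMRCAs with the rho statistic (Saillard standard deviation, mutation-rate
    confidence propagation), dates clades from Y-STR profiles by rho and
    average squared distance (ASD) under ancestral or modal roots and several
    marker subsets and rate regimes, tests branch-length heterogeneity with a
    subsampled pairwise Mann-Whitney protocol, tests for singleton enrichment
    among damaging variants (purifying selection), summarises SNP recurrence
    and CpG context, and ships a male-genealogy simulator (coalescent or star,
    Poisson SNP mutations, single-step STR mutations, optional finite-sites
    recurrence and cell-line somatic singletons) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
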