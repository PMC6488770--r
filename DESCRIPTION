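Package: relateGL
Title: Relatedness and Inbreeding from Genotype Likelihoods
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the nine condensed Jacquard
    identity coefficients for a pair of possibly inbred diploid individuals
    directly from per-site genotype likelihoods, without calling genotypes.
    The composite likelihood over unlinked biallelic sites is maximised by
    SQUAREM-accelerated expectation-maximisation on the probability simplex,
    with multi-start support, boundary examination and site-level bootstrap
    confidence intervals. Derived summaries include relatedness, kinship and
    per-individual inbreeding coefficients, plus allele-frequency-free
    identity-by-state statistics (R0, R1, KING-robust kinship) from the
    pairwise two-dimensional site frequency spectrum estimated by EM from the
    same genotype likelihoods. A pedigree gene-dropping simulator with an
    exact condensed-identity-coefficient oracle generates validation data.
    Input formats: beagle genotype-likelihood tables, plain-text frequency
    files and VCF (GL or PL tags).
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
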