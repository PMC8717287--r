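Package: mimicline
Title: Hybrid-Zone Cline Analysis for a Bumble Bee Mimicry Transition Zone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a Muellerian mimicry transition zone in the
    bumble bee Bombus melanopygus: dominance-aware colour-allele frequency
    estimation under haplodiploidy, equilibrium geographic cline models fitted
    by Metropolis-Hastings MCMC with AICc model selection, mito-nuclear
    discordance goodness-of-fit tests, COI haplotype statistics and
    minimum-spanning haplotype networks, tiered NUMT-aware SNP filtering with
    fixed-SNP clustering diagnostics, and nuclear structure inference
    (neighbour joining, LD pruning, PCA, sNMF-like NMF admixture). A synthetic
    hybrid-zone generator provides specimen tables, COI alignments and SNP
    matrices with the statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    geosphere,
    ape,
    igraph,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
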