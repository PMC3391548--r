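Package: pyroqc
Title: Quality-Score Refinement and Diversity Assessment for Amplicon Pyrosequencing Reads
Version: 0.1.0
Authors@R:
    person("pkg", "maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quality-score based refinement of SSU rRNA gene
    amplicon reads from 454-style pyrosequencing: length trimming, Phred
    cutoff filtering with a tolerated fraction of sub-threshold bases,
    quality-based end trimming, ambiguous-base and primer-error removal
    with per-stage removal ledgers; complete-linkage OTU clustering from
    pairwise alignment distances; alpha-diversity statistics (analytic
    rarefaction, Chao1 with 95 percent confidence intervals, Shannon
    diversity and Pielou evenness); assessment of phylogenetic bias in
    sequence removal; homopolymer-run tabulation; and a seeded synthetic
    read simulator with ground truth that emulates pyrosequencing quality
    decay, substitution errors tied to Phred probabilities, and
    homopolymer length errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
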