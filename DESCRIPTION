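Package: fluctproof
Title: Fluctuation-Assay Mutation Rates and Replicative Polymerase
    Proofreading Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Luria-Delbruck fluctuation analysis for yeast reversion
    assays: maximum-likelihood estimation of mutations per culture under
    the Ma-Sandri-Sarkar recursion, profile-likelihood confidence
    intervals at arbitrary coverage, and confidence-interval-overlap
    significance rules. On top of the rate machinery the package encodes
    the deterministic mapping from trp5 reporter allele and gene
    orientation to the replication strand and template/primer mispair
    responsible for reversion, a mechanistic replication-fork error model
    (misinsertion, mispair extension, polymerase dissociation and rescue
    by wild-type Pol delta, mismatch repair) that serves as the synthetic
    data generator, heterozygote/homozygote ratio inference of the
    fraction of polymerase errors rescued by proofreading in trans or in
    cis, and exact Mann-Whitney rank-sum analysis of oligonucleotide
    transformation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
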