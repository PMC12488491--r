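Package: clonecn
Title: Clone-Level Allele-Specific Copy Number Inference on Fixed Tumour Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers integer, allele-specific copy numbers for every clone of a
    fixed tumour phylogenetic tree from multi-sample bulk fractional copy-number
    estimates and clone proportions. Each genomic segment is solved exactly by a
    branch-and-bound search under a copy-number evolutionary model (irreversible
    loss of heterozygosity, bounded gain/loss alternation along root-to-clone
    paths) with lexicographic objectives and elbow-based model selection over the
    event budget. Includes a multi-sample bulk simulator with Poisson read-depth
    and binomial B-allele-frequency noise, preprocessing rules for fractional
    copy-number tables (clonality and allelic-imbalance tests, allele
    rebalancing, homozygous-deletion eligibility), downstream clone-level
    analytics (ploidy, whole-genome doubling, edge event calling at segment and
    arm level, SCNA counting, clone classification, clone copy-number
    diversity), and benchmark metrics (state-set accuracy, matched-clone Hamming
    distance, total variation distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
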