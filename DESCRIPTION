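Package: cdcoca
Title: Complexity-Corrected Co-Occurrence Analysis of Copy Number Alterations
Version: 0.1.0
Authors@R:
    person("cdcoca", "authors", email = "tools@example.org", role = c("aut", "cre"))
Description: Permutation testing for co-occurring somatic copy-number
    alterations (CNA) across tumor cohorts at cytogenetic band resolution.
    Implements the CDCOCA statistic: the overlap of two CNA categories
    (measured by Jaccard's index) is compared against a null in which each
    category's carrier count is preserved and carriers are redrawn without
    replacement with probability proportional to each sample's overall CNA
    burden, so that co-occurrences explained by genomically complex samples
    are discounted. A uniform-weight variant (CICOCA), an exact enumeration
    oracle for small instances, empirical false-discovery-rate estimation at
    a p-value cutoff, segment-to-cytoband mapping, a synthetic cohort
    generator with planted associations, and a command line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
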