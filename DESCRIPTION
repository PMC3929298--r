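Package: triodel
Title: De Novo Deletion Detection and Association Testing in Case-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-wide pipeline for detecting de novo deletions in
    case-parent trios from SNP-array intensities (log R ratios and B allele
    frequencies) and testing whether they occur more often in affected
    probands. Implements trio-level intensity quality control, a
    minimum-distance de novo deletion caller built on circular binary
    segmentation, delineation of overlapping calls into state-homogeneous
    CNV components, component-level one-sided Fisher tests with
    permutation-based family-wise error control, deletion-width comparison
    statistics (one-sided Kolmogorov-Smirnov and Wilcoxon rank-sum tests,
    simulated quantile-quantile envelopes), and a synthetic trio-intensity
    generator with planted deletions, genomic waves and DNA-source-dependent
    noise so the whole pipeline can be exercised without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
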