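Package: tissuemix
Title: Detecting Paternal Genome Elimination from Tissue-Mixture Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect paternal genome elimination (PGE) from a single
    whole-body male sequencing library. Fits a two-component negative-binomial
    model to k-mer (or mapping) coverage histograms to locate the 1n and 2n
    peaks, converts the peak ratio into the fraction of haploid germline tissue
    (sperm) under a two-tissue mixture model, decomposes heterozygous allele
    depths into major and minor components and compares them with X-linked
    haploid coverage, and provides an independent SNP-call-free estimate from
    raw pileup bistate frequencies. Includes coverage-based scaffold sex
    assignment and a synthetic-data generator with known ground truth for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    minpack.lm,
    mclust,
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
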