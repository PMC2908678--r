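Package: ancestryShift
Title: Ancestry-Shift Refinement Mapping of Case-Control Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Refinement mapping of case-control association signals by
    shifting the analysis between ancestral populations whose linkage
    disequilibrium fractionates a locus differently. From phased reference
    panels the package screens SNPs correlated with an index signal,
    partitions them into r-squared equivalence classes by average-linkage
    clustering, tests allelic association under the multiplicative model
    with genomic-control correction and likelihood recovery of missing
    genotypes, adjusts SNPs for one another by conditional logistic
    analysis, combines effects across ancestries with Mantel-Haenszel and
    inverse-variance models plus likelihood-ratio heterogeneity and I2
    diagnostics, and estimates multilocus haplotype frequencies and odds
    ratios by trio-aware EM. A retrospective multi-ancestry simulator,
    seeded from published haplotype-frequency pools at the C6orf97/ESR1
    locus, exercises the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'assoc.R'
    'esr1-data.R'
    'expr.R'
    'hapfreq.R'
    'io.R'
    'ld.R'
    'meta.R'
    'pipeline.R'
    'simulate.R'
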