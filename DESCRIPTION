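Package: mirLOH
Title: miRNA Sensitizer Screen Hit Calling and Copy-Neutral LOH Analysis in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two linked analyses around miRNA-mediated suppression of
    homologous recombination. First, plate-based miRNA-mimic screen analysis:
    per-plate negative-control normalisation, Z-scores, percent-control
    viability, toxicity filtering against a BRCA2-siRNA comparator, and ranked
    sensitizer hit calls. Second, tumor-cohort genomics: classification of LOH
    events into deletion-mediated versus copy-neutral under either an
    aCGH-segment overlap rule or a SNP-marker allelic-copy-number rule,
    genotyping of miRNA loci for deletion/neutral/amplification, assignment of
    WT versus per-miRNA deletion groups, and one-tailed Mann-Whitney
    comparisons of per-sample LOH burden, somatic copy-number event burden and
    gene expression between groups. A synthetic-data module simulates screen
    plates and tumor cohorts with planted ground truth so every stage is
    testable end to end, and a small duplex utility implements Watson-Crick +
    G:U wobble pairing and the canonical seed-site test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, Sequencing, StatisticalMethod, Software
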