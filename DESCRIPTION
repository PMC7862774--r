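Package: bulkscan
Title: Bulked-Segregant QTL-Seq Mapping with Pooled Allele-Frequency Scans
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative trait loci from bulked-segregant whole-genome
    sequencing (QTL-seq) of an F2 population. Computes per-site SNP-index and
    delta(SNP-index) statistics from pooled allele depths in a multi-sample VCF,
    smooths them with a sliding-window genome scan, derives resampling-based
    confidence thresholds for the pooled allele-frequency difference, and calls
    candidate QTL regions which are then intersected with GFF3 gene models.
    Includes phenotype scoring of rice spikelet fertility with extreme-tail bulk
    selection, a fully parameterised F2 bulked-segregant data simulator with
    known ground truth for end-to-end validation, and 2^-ddCt relative-expression
    analysis of qPCR threshold cycles for candidate genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
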