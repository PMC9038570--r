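Package: dmbtsel
Title: Balancing Selection and SRCR Copy-Number Haplotypes at DMBT1
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dissecting the balancing-selection
    footprint at the 5' end of the human DMBT1 gene. Computes Tajima's D
    from phased haplotypes with a genome-wide 10 kb window scan and
    per-population z-normalization, partitions the selected region into
    its two divergent haplotype clades with a tag SNP, phases multiallelic
    SRCR tandem-repeat copy-number alleles onto SNP haplotypes by pedigree
    constraint propagation and by trio expectation-maximization, tests the
    association between clade and repeat-allele distributions, models
    salivary DMBT1 protein isoform size from diploid SRCR copy number and
    FUT2 secretor status, and counts complete SRCR repeat units in
    long-read transcript exon chains. A synthetic-data module emulates the
    statistical structure of every input (neutral coalescent windows,
    two-clade balanced regions, CEPH-style pedigrees and trios, PRT-style
    copy-number measurements, isoform panels, transcript reads) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
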