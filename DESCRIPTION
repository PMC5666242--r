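Package: quartetflow
Title: Four-Taxon Gene-Flow Statistics from Multi-Sample Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for detecting introgression between
    lineages from whole-genome genotype data of a four-taxon quartet
    (H1, H2, H3, outgroup). Reads multi-sample VCF files, applies
    depth, indel-proximity and repeat-interval filters, performs
    sex-aware X-chromosome haploidization by depth of coverage with
    male pseudo-heterozygote exclusion and a pseudoautosomal split,
    polarizes sites against an outgroup, tallies frequency-weighted
    ABBA/BABA/BBAA site patterns and tri-allelic CBBA/BCBA/CCBA
    patterns in genomic windows, and computes Patterson's D and the
    windowed f_dM admixture statistic with significance from a
    weighted block jackknife. Includes pairwise sequence divergence
    summaries and a synthetic four-taxon genotype generator with
    known incomplete-lineage-sorting and introgression structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    IRanges,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
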