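Package: poolscan
Title: Genotype-Environment Association Scans for Pooled Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scanning pooled-sequencing (pool-seq) allele counts for
    association with an environmental gradient. Reads PoPoolation2-style sync
    files, reduces sites to biallelic SNPs, applies coverage and minor-allele
    filters, estimates among-pool covariance of standardized allele
    frequencies, scores each SNP with a covariance-whitened absolute Spearman
    rank correlation against a standardized environmental variable, and
    assigns empirical false discovery rates at SNP and gene (supertranscript)
    level from a label-permutation null. Includes a synthetic pooled-read
    generator (finite pool resampled to reads, with optional planted
    temperature-associated genes) so every stage of the pipeline can be
    exercised and calibrated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
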