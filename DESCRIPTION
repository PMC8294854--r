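Package: radmix
Title: Local-Ancestry Inference and Introgression Analysis for Sparse RAD-Seq Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed pairwise-divergence counting between diploid samples,
    a three-state binomial-emission hidden Markov model (native, donor,
    heterozygous ancestry) decoded by log-space Viterbi, ancestry-block
    extraction and age estimation, admixture mapping of local ancestry
    against binary phenotypes, and supporting population-genetic statistics
    (Watterson's theta, nucleotide diversity, Tajima's D, folded and
    projected site-frequency spectra with introgression masking, Patterson's
    ABBA-BABA D with block bootstrap, demographic-unit rescaling). Includes
    a synthetic ddRAD-like diploid genotype generator with planted donor
    tracts and full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
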