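Package: radseqsim
Title: Simulation and Evaluation of RADseq Genome Reduction for Genomic
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate restriction site-associated DNA sequencing
    (RADseq) strategies as low-cost alternatives to low-density SNP chips
    in genomic selection programs. The package simulates in silico
    restriction digestion of a genome with one enzyme (GGRS-style) or two
    enzymes (ddRADseq), predicts sequencable fragments and paired-end read
    windows, intersects the predicted windows with a marker set and a
    high-density SNP panel, quantifies how polymorphisms that create or
    destroy recognition sites perturb the predicted fragments, and carries
    the resulting reduced marker panels through genotype quality control,
    haplotype-library imputation to high density, and single-step GBLUP
    genomic evaluation with ranking comparisons of selection candidates.
    A self-contained generator produces pedigreed populations with
    LD-structured haplotypes, chromosome classes of differing size and GC
    content, polygenic traits and a high-density panel, so the whole
    pipeline runs end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
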