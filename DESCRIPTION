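Package: homeoquant
Title: Homeolog-Aware Quantification of Methylation and Expression in
    Allotetraploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies DNA methylation (MeDIP-seq) and gene expression
    (RNA-seq) in allotetraploid species by mapping reads against both
    diploid sub-genomes jointly. Ortholog pairs between the sub-genomes are
    detected by reciprocal-best protein similarity confirmed by 100 kb
    synteny blocks and merged into single quantification units; reads are
    classified by their joint mapping status (one sub-genome, both, or
    neither) and counted once per merged gene to avoid double counting of
    homeologous reads. Region-wise RPM quantification (promoter, gene body,
    downstream region, CpG islands and shores), replicate t-test
    differential calls, methylation-expression integration, small-RNA
    target-locus association, and a ground-truth simulator for two diverged
    sub-genomes are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
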