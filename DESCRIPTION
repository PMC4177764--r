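Package: phagecomp
Title: Comparative Genomics of T4-Like Bacteriophage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation statistics, cumulative GC-skew replication-origin
    prediction, codon-usage and tRNA-optimality analysis, pairwise-alignment
    homolog and core-genome detection, duplication-versus-convergence
    classification, split-gene detection and synteny mapping for T4-like
    bacteriophage genomes, together with a synthetic phage-genome generator
    that plants known origins, gene families, duplications, splits and
    inversions so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
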