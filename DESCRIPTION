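Package: palmotif
Title: Stage-Transition Expression Motif Analysis for Palatal RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies staged RNA-seq expression profiles into nine
    stage-transition motifs (up / down / unchanged over two consecutive
    developmental transitions, called at a fold-change threshold on
    log10(FPKM+1) values) and compares motif membership across TGFb3
    genotypes to nominate candidate cleft-palate genes. Includes a curated
    322-gene cleft-palate panel, mouse/human panel merging through an
    ortholog map, replicate-concordance quality control, Venn-style gene-set
    partitions, differential-set tabulation, pattern-grouped heatmaps, and a
    synthetic FPKM generator with planted pattern truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    grDevices,
    jsonlite,
    pheatmap,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
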