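Package: mosaiceqtl
Title: Founder-Haplotype eQTL Mapping and Co-Expression Networks for
    Multiparent Mosaic Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, self-contained pipeline for expression QTL analysis
    in multiparent populations such as Diversity Outbred mice: simulation
    of founder-haplotype mosaic genomes with known ground truth,
    RNA-seq count preprocessing (TMM normalization, logCPM, contamination
    residualization, sex-chromosome aneuploidy flagging, sample-mixup
    resolution by Hungarian assignment on haplotype-probability
    correlations), linear mixed-model genome scans with leave-one-
    chromosome-out kinship, LOD peak calling with cis/trans
    classification, founder allele effects, heritability estimation,
    SNP association via strain distribution patterns, conditional-LOD-drop
    mediation, and robust co-expression analysis (biweight
    midcorrelation, signed soft-threshold networks, topological-overlap
    modules, paraclique extraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    clue,
    edgeR,
    igraph,
    jsonlite
Suggests:
    limma,
    withr,
    mclust,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
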