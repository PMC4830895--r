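Package: hepadyn
Title: Quantitative Dynamics of Nrf2 and NF-kB Stress Responses in Hepatocyte Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug-induced stress-response dynamics in hepatocyte
    reporter cell lines from live-cell imaging and companion transcriptomics.
    Provides single-cell NF-kB (GFP-p65) nuclear translocation oscillation
    analysis from nuclear/cytoplasmic intensity ratio traces (segmentation,
    tracking, peak detection, inter-peak delay statistics), Srxn1-GFP reporter
    induction scoring, Annexin-V death-curve quantification with a drug-TNFa
    cytotoxic synergy statistic, and gene-set filtering, Manhattan/Ward
    clustering and Fisher-exact pathway enrichment of differential-expression
    tables. A synthetic-data generator with known ground truth emulates the
    microscopy and expression inputs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    fgsea,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
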