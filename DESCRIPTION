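Package: smfishq
Title: Quantification of Single-Molecule RNA FISH Z-Stacks in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns interleaved multi-channel single-molecule RNA FISH
    (smFISH) z-stacks of budding yeast into per-cell nuclear and
    cytoplasmic transcript counts and population statistics. Nuclei are
    segmented in 3D from the DAPI channel with cell-specific thresholds,
    whole cells from the widefield channel with a seeded watershed, and
    diffraction-limited mRNA spots per dye channel with Gaussian
    denoising, Laplacian-of-Gaussian filtering and regional-maximum
    localization. Downstream statistics include the population mean,
    ON-fraction against a basal cumulative cutoff, Fano factor, and
    marginal and joint nuclear-cytoplasmic count distributions. A seeded
    synthetic field generator renders four-channel stacks with full
    ground truth so the whole pipeline is testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
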