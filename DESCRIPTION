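Package: fernquant
Title: Quantitative Analysis of Apical-Cell-Driven Fern Gametophyte Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying apical-cell (AC) driven growth in fern
    gametophytes from two-timepoint membrane-stain microscopy. Provides a
    synthetic prothallus simulator that grows a single-layered polygonal
    tissue from a seeded three-celled apical packet using oriented
    (oblique, periclinal, anticlinal) cell divisions and region-dependent
    stochastic division and expansion, and renders membrane-stain image
    pairs with ground-truth label masks and lineages; marker-based
    watershed segmentation of membrane-stained images; overlap-based cell
    lineage matching and division calling between 0 and 48 hr; and the
    centre-of-meristem versus outside quantification (percentage of cells
    divided, relative total cell area, per-cell relative growth,
    colour-coded maps, Student's two-tailed t-tests), together with an
    end-to-end pipeline and a parameter-recovery experiment on synthetic
    microscopy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
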