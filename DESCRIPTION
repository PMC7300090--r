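Package: histoquant
Title: Quantitative Histology of Tumor Microenvironment Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for brightfield and polarized-light
    histology of the tumor microenvironment. Extracts individual collagen
    fibers from picrosirius-red (PSR) birefringence images and summarizes
    their angle, length and width distributions with axial circular
    statistics; quantifies collagen bundling through hue-bin analysis of PSR
    signal and blue/red pixel ratios of Masson's trichrome; performs
    Beer-Lambert stain deconvolution of dual-chromogen immunohistochemistry
    (hematoxylin, DAB, Vector Red), segments cells into nuclear, membrane and
    cytoplasmic compartments, gates tumor cells by cytokeratin-18/Vector Red,
    and applies per-marker subcellular positivity rules (nuclear, complete
    membrane, membrane-or-nuclear, area-fraction, membrane-plus-cytoplasm);
    measures spheroid diameter and growth and counts vessel lumens. A
    synthetic-histology generator renders every supported modality with
    exhaustive ground truth, so each pipeline stage is validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'color-analysis.R'
    'core-io.R'
    'fiber-architecture.R'
    'histoquant-package.R'
    'ihc-quant.R'
    'morphometry.R'
    'stats-report.R'
    'synthetic.R'
    'utils-internal.R'
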