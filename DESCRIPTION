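Package: trnamrm
Title: Scheduled-MRM Quantification of tRNA Ribonucleoside Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative profiling of transfer RNA ribonucleoside
    modifications by scheduled multiple-reaction-monitoring (MRM) LC-MS/MS.
    Ships the acquisition transition registry for the yeast cytoplasmic tRNA
    ribonucleoside transitions (retention times, parent and product m/z,
    voltages, acquisition segments), integrates chromatographic peaks,
    normalizes signal to a stable-isotope internal standard and tRNA mass,
    fits external calibration curves for absolute quantification, computes
    exposure-signature statistics (fold-changes with Student's t-tests,
    centroid-linkage hierarchical clustering on Pearson distances,
    correlation-matrix PCA with per-observation contributions), and analyzes
    deletion-mutant ratio matrices to infer enzyme-product links and
    methyltransferase redundancy. A synthetic scheduled-MRM chromatogram
    generator with known ground truth makes the whole pipeline testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
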