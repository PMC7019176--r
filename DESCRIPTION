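Package: pdtvasc
Title: Quantitative DCE-MRI Pharmacokinetics and Fluorescence Analysis of
    Tumor Vascular Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify tumor vascular response to photodynamic
    therapy from dynamic contrast-enhanced MRI, intravital fluorescence
    microscopy and histology. Implements variable flip angle T1 mapping,
    conversion of spoiled gradient-echo signal to gadolinium contrast-agent
    concentration, enhancement classification, voxelwise Tofts-Kermode
    pharmacokinetic fitting with a fixed bi-exponential arterial input
    function, ROI-level summary statistics, background-corrected integrated
    fluorescence densities with inverse-variance weighted means and Spearman
    colocalization, and Hoechst-threshold perfusion / necrosis fractions.
    A synthetic digital phantom with known ground truth supports end-to-end
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
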