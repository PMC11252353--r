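Package: fpolcyto
Title: Automated Fluorescence Polarization Cytology of Thyroid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated analysis pipeline for fluorescence polarization
    (Fpol) cytology of methylene-blue stained thyroid fine-needle aspirates.
    Provides synthetic polarized-image phantom generation with ground-truth
    masks, an encoder-decoder (U-Net) semantic segmentation network trained
    on a three-class labeling scheme (background, ambiguous cell signal,
    high-quality cells), binary morphological post-processing, per-cell
    Fpol and area quantification from co- and cross-polarized image pairs,
    automated-versus-manual segmentation agreement metrics, and grouped
    significance testing with Bonferroni correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
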