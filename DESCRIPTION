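Package: octnss
Title: Neutrosophic Similarity Score Enhancement for Retinal OCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrast enhancement of retinal optical coherence tomography
    (OCT) images in the neutrosophic domain. Each pixel is mapped to truth,
    indeterminacy and falsity memberships, scored by its cosine similarity
    to the ideal bright, unambiguous pixel, and the resulting similarity map
    is contrast-limited adaptive histogram equalized (CLAHE) and defuzzified
    back to the source intensity range. Includes image quality metrics
    (PSNR, SSIM, Shannon entropy and entropy improvement), multi-class
    classification reports with one-vs-rest ROC/AUC, a seeded generator of
    layered-retina speckle phantoms covering eight lesion archetypes, and a
    two-stage transfer-learning harness (frozen backbone, then partial
    unfreezing at a reduced learning rate) with a small pure-R convolutional
    backbone for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jpeg,
    pROC,
    stats,
    utils,
    tools
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
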