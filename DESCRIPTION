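Package: rimquant
Title: Quantification of Peritumoral Fluorescence Rims in Ex Vivo Liver Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify indocyanine-green (ICG) near-infrared
    fluorescence around colorectal liver metastases in ex vivo bread-loaf
    images. Builds distance-banded masks (peritumoral rim up to 3 mm,
    exclusion gap, parenchymal background from 5 mm) from tumor and tissue
    annotations, computes the mean signal and background fluorescence
    intensities, their ratio, and the maximum intensity, and applies the
    stasis-override and background-pooling recalculation rules. Includes
    RECIST 1.1 response and Brunt steatosis classifiers, a cohort-level
    statistical layer (two-group and multi-group tests, rank correlation,
    multiple linear regression), and synthetic phantom and cohort
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
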