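Package: mandicort
Title: Mandibular Cortical Bone Morphometry and Osteoporosis Screening from Panoramic Radiograph ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computer-aided assessment of mandibular cortical bone on dental
    panoramic radiograph regions of interest (ROIs). Enhances the bright
    inferior cortical band with a multiscale line operator, segments it by
    seeded statistical region merging, models the upper border with a
    polynomial and measures cortical width perpendicular to the border
    tangent, extracts a porosity-sensitive mean-intensity texture feature,
    and classifies subjects into normal, osteopenia and osteoporosis groups
    with a multiclass radial-basis-function support vector machine under
    stratified k-fold cross-validation. Includes segmentation error metrics
    (misclassification error, relative foreground area error), screening
    diagnostics, and a phantom-image generator producing class-conditional
    ROI pairs with ground truth so the whole pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
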