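Package: icmkaryo
Title: Image-Cytometry Chromosomal DNA Sizing and Karyotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromosomal DNA sizing by Feulgen image cytometry
    anchored to a flow-cytometric nuclear 2C value. Converts calibrated
    brightfield metaphase images to optical-density maps, qualifies the
    imaging setup (linearity, uniformity, stability), segments and measures
    individual chromosomes (medial axis, width profile, centromere and
    secondary constriction, arm and satellite partitions, integrated optical
    density), allocates the nuclear DNA amount proportionally to
    per-chromosome, per-arm and per-satellite integrated optical density,
    and assembles karyograms and ideograms. Includes a synthetic metaphase,
    calibration-target and flow-histogram generator with exact ground truth
    for validation, parameterised as a maize-like 2n = 20 complement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
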