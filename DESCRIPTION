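Package: placentaq
Title: Quantification of Placental Contrast-Enhanced MRI Dynamics,
    Histology and Expression Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying placental function and senescence
    phenotypes across three complementary assays. For dynamic
    contrast-enhanced MRI, extracts region-of-interest signal-intensity
    time series and computes landmark statistics of the biphasic placental
    enhancement curve: initial enhancement (first maximum over baseline),
    recovery (second maximum over the interior minimum) and the rate of
    enhancement scaled to the vena cava signal. For histology, implements
    percent-positive syncytia counting, a nine-level semi-quantitative
    Ki67 proliferation rubric, trophoblast fusion indices, and
    threshold-based area-fraction quantification of staining or
    gelatinolytic activity. For expression data, a linear fold-change
    filter between culture stages, plus the group comparisons (pooled
    t-test, one-way ANOVA with Tukey HSD) used throughout. A synthetic
    data generator with known ground truth makes every stage testable
    without access to scanner or microscope data, and a pipeline driver
    ties the stages into a reproducible, manifest-tracked run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
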