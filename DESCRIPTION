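Package: rbcdi
Title: Red Blood Cell Deformability Analysis for Microfluidic Brightfield Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies red blood cell (RBC) deformability from brightfield
    images of cells elongating in microfluidic shear flow. Implements two
    complementary image-analysis pipelines -- a sine-window background
    subtraction workflow with least-squares ellipse fitting, and a
    Difference-of-Gaussians plus horizontal top-hat workflow with scaled Otsu
    segmentation and farthest-point axis measurement -- both reporting the
    per-cell deformability index DI = (L_X - L_Y)/(L_X + L_Y). Includes
    per-image and per-donor aggregation, shear stress to shear rate
    conversion, a statistical layer for donor-group comparison (Mann-Whitney,
    linear mixed-effects models with Satterthwaite degrees of freedom and
    partial eta squared, Pearson correlation, Bland-Altman agreement), and a
    synthetic image and cohort generator with ground truth for validating the
    whole system without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
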