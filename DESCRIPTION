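Package: otomorph
Title: Otolith Morphometry and Vestibular Function Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A measurement chain for quantifying age-related change in the
    otolithic organs of the inner ear. Implements micro-CT otolith
    segmentation with a midpoint threshold derived from paired regions of
    interest, volume and mean CT-number quantification, a dual-threshold
    striola edge-volume statistic, the otolith layer angle from traced
    electron-microscopy point sets, and the otolith function index computed
    from linear-sled position and axis-angle eye-movement traces recorded
    during the linear vestibulo-ocular reflex. Ships synthetic-data
    generators (otolith phantoms, trapezoidal sled profiles, eye traces,
    layer tracings, and age-by-sex cohorts) so the whole pipeline is
    testable without animal data, plus the study's statistical pathway:
    normality screening, two-way ANOVA with Type III sums of squares, and
    Bonferroni-corrected post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    yaml,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
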