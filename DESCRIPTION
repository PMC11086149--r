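Package: gaitoverlap
Title: Distributional Overlap of In-Lab and Real-World Running Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies how well one distribution of running gait patterns
    represents another, using per-metric quantile-coverage overlap and
    multivariate Tukey (half-space) depth with the random-direction
    approximation. Includes a synthetic-data generator for wearable-sensor
    gait records and GNSS traces with known terrain segments, GPX and
    delimited-table input/output, turn-rate and grade computation with
    data-driven flat-and-straight segmentation thresholds, and a
    subject-wise bootstrap pipeline comparing in-lab, measured-course, and
    free-living running across cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    MASS,
    Matrix,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
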