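Package: portalQA
Title: Dose-Comparison Inputs for Deep-Learning Error Identification in
    Pre-Treatment Radiotherapy QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates arc treatment plans (VMAT- and SBRT-like) and
    surrogate time-integrated 2D portal-dose images, injects the five
    classical mechanical delivery errors (collimator rotation, systematic
    and random multileaf-collimator shifts, systematic and random monitor
    unit scaling), computes twelve 2D dose-comparison image variants
    (five global gamma criteria, ratio, absolute and relative dose
    difference, signed distance-to-agreement maps, a DD/DTA stack,
    structural similarity, and Sobel gradient maps), preprocesses them
    (10% low-dose crop, dataset normalization, square resize), and trains
    small convolutional classifiers to identify error type and error
    relevance over the full factorial design of comparison method,
    normalization and resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
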