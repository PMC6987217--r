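Package: hmpdev
Title: Habitual Motion Path Deviation Analysis for Knee Kinematics and
    Cartilage Response
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the knee joint habitual motion path (HMP) from
    half-squat kinematics, the deviation from that path during treadmill
    running in different footwear conditions, and relates the deviation to
    pre/post-run cartilage volume reductions in seven knee sub-regions.
    Includes least-squares rigid-body pose estimation from marker clouds,
    Cardan angle decomposition, stance and eccentric phase detection, a
    statistical battery (exact one-tailed Wilcoxon rank-sum, dependent-sample
    t-tests, simple linear regression, Cohen's d with unweighted variance
    pooling), and a fully seeded synthetic-cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
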