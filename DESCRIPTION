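Package: feedkin
Title: Feeding-Movement Kinematics: Phase Segmentation, Hand Metrics, and
    Paired Utensil Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for upper-body kinematics of eating movements
    recorded as joint-angle and hand-position time series. Segments eating
    cycles into the four feeding phases (reaching, table, transporting,
    mouth) from hand-landmark proximity events, summarises per-phase joint
    angles (maximum, minimum, range of angle change, movement time),
    computes transporting-phase hand spatiotemporal parameters (actual and
    relative distance travelled, mean and maximum velocity, timing of
    maximum velocity, and the movement-unit smoothness count), and compares
    paired utensil conditions (chopsticks vs spoon) with Wilcoxon
    signed-rank tests and effect size r. A minimum-jerk synthetic
    feeding-motion generator with recorded ground truth makes every stage
    testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
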