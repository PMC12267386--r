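Package: vrreach
Title: Go/No-Go Reaction-Time Protocols, Reach Kinematics, and Method-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for a computerized and virtual-reality go/no-go
    reaction-time instrument. Generates randomized trial schedules for simple and
    choice reaction-time phases and for body-scaled three-dimensional reach tasks
    (Press, Center, Spatial, Dynamic), constructs the calibrated nine-location
    stimulus grid from sternum and extended-arm anchors, simulates synthetic
    participants with ex-Gaussian response latencies and minimum-jerk reach
    trajectories, scores time-stamped session event logs into per-trial records
    and per-task summaries (reaction time, movement time, movement velocity,
    intra-individual coefficient of variation, anticipation, omission and
    false-alarm rates) with the instrument's validity cutoffs, and provides the
    validation statistics used for method agreement: Pearson correlation,
    Bland-Altman limits of agreement, Wilcoxon signed-rank and Friedman tests,
    repeated-measures ANOVA with Greenhouse-Geisser correction, Bonferroni
    adjustment, and exact power analysis for a Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
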