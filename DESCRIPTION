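Package: primetrial
Title: Neuromuscular Assessment Analysis for Spinal Cord Stimulation Priming Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing and statistical analysis for randomized crossover
    sham-controlled neuromuscular priming experiments using spinal cord
    transcutaneous stimulation. Processes raw torque, force, velocity and surface
    EMG recordings into outcome variables (maximal voluntary contraction torque,
    rate of torque development, torque steadiness, explosive lower-limb power,
    EMG amplitude and median power frequency), characterizes evoked-potential
    recruitment curves (peak-to-peak amplitude, activation threshold,
    normalization), and runs the 2x2 within-subject crossover analysis
    (repeated-measures ANOVA, Bonferroni post hoc, paired tests on percent
    changes, effect sizes, matched-pairs power). A synthetic-data generator
    emulates the trial signals and cohort effect structure so the whole chain is
    testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
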