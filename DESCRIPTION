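Package: stumblr
Title: Stumble-Recovery Analysis for Treadmill Perturbation Trials of
    Lower-Limb Prosthesis Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse stumble-recovery responses of lower-limb
    prosthesis users to split-belt treadmill perturbations: zero-phase
    filtering and body-weight normalisation of marker and force-plate
    series, coordinate-based gait-event detection, segmentation of the
    perturbation and three recovery steps, trunk angular sway, peak trunk
    flexion angular velocity and first-peak ground-reaction-force
    extraction, trial screening (warm-up, onset phase, handrail grabs,
    marker completeness, belt separation), and a mixed-design
    repeated-measures ANOVA layer with Mauchly's sphericity test,
    Greenhouse-Geisser correction, Bonferroni post-hoc comparisons and a
    Welch contrast on recovery-step asymmetry. A synthetic treadmill-trial
    generator with full ground-truth annotation exercises every stage
    without recorded data, and a small closed-loop module emulates the
    insole-pressure-to-stimulation mapping of a plantar sensory
    neuroprosthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    ggplot2
Config/testthat/edition: 3
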