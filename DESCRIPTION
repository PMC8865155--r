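Package: simbias
Title: Simulation and Analysis Pipeline for Automatic-Imitation Kinematics and
    Prefrontal fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the complete analysis path of a within-participant
    automatic-imitation experiment with prefrontal functional near-infrared
    spectroscopy (fNIRS): extraction of rhythmical movement cycle times from
    3-D hand kinematics (zero-phase Butterworth smoothing, peak detection,
    windowed cycle-time averaging) and the slow:fast imitation-bias ratio;
    fNIRS processing from raw two-wavelength optical intensities to
    hemisphere-level oxygenation scores (FIR low-pass filtering,
    sliding-window motion-artifact rejection, the modified Beer-Lambert law,
    capture-window averaging, change scores relative to action observation);
    and the repeated-measures inferential layer (paired t, one- and two-factor
    repeated-measures ANOVA with Mauchly's test and Greenhouse-Geisser
    correction, Bonferroni pairwise comparisons, generalized and partial eta
    squared, and a-priori power via the noncentral F distribution). A
    synthetic-data generator emulates the factorial design and embeds known
    ground-truth effects in raw signals via a forward Beer-Lambert model, so
    every stage is testable end to end without any recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
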