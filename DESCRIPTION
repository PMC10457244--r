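Package: swaybins
Title: Event-Related Bin Statistics of Force-Plate Sway During Response
    Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-related pipeline for posturography: zero-phase
    Butterworth filtering of force-plate moment time series, trigger-pulse
    decoding of trial events, segmentation into labelled Simon-task trials
    with behavioural exclusion rules, target- and response-aligned 150 ms
    bin statistics (absolute average and standard deviation of the centred
    ground-reaction-force moment), and within-subject inference (paired t
    tests with dz, repeated-measures ANOVA with partial eta squared, paired-t
    power from the noncentral t distribution). A synthetic session generator
    produces Simon-task schedules, reaction times and error rates with
    congruency-sequence structure, trigger channels, and two-timescale sway
    with phase- and congruency-locked variability modulation, so the whole
    chain can be exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
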