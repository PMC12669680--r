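Package: oculaware
Title: Stimulus-Evoked Eye-Metric Analysis for Studies of Visual Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visual stimulus-evoked pupil size, blink and
    microsaccade responses in eye-tracking studies of conscious awareness,
    with an emphasis on cerebral blindness designs that contrast a sighted
    and a blind hemifield. Provides a synthetic session generator with
    controllable evoked structure; blink detection and pupil cleaning;
    median-velocity-threshold microsaccade detection; stimulus- and
    blank-locked epoch extraction with baselining and exclusion rules;
    two-level stacked linear support-vector-machine classification of
    stimulus versus blank epochs under nested cross-validation; behavioural
    scoring (perception rate, orientation accuracy, false positives, exact
    binomial tests); brightness-comparison scoring with Friedman and
    signed-rank follow-ups; a luminance-ordered pupil constriction slope
    test; and cluster-based permutation testing of evoked field potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
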