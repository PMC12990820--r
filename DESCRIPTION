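Package: freqtagsl
Title: Frequency-Tagging Analysis of Visual Statistical Learning EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for steady-state visual evoked
    potential (SSVEP) frequency-tagging studies of statistical learning.
    Generates stimulus streams with controlled transitional-probability
    structure (doublet, control and random conditions), synthesizes
    multichannel EEG with occipitally weighted steady-state responses over
    1/f background noise, and analyses recordings end to end: average
    re-referencing, noisy-channel repair, trigger-based segmentation,
    amplitude spectra and signal-to-noise ratios at tagged frequencies,
    valid-trial selection, Wilcoxon harmonic selection, permutation maximum
    statistics for sensor-space localization, and a trial-level linear
    mixed-model ladder with simple-coded condition contrasts, Tukey post
    hocs and ICC reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
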