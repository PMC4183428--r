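Package: wakeprob
Title: Wake Probability Modeling of the Sleep Onset Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking the sleep onset process as a continuous,
    probabilistic transition rather than a single staged event. Implements a
    Bayesian state-space model that fuses occipital EEG band powers (alpha and
    delta-theta), EMG squeeze amplitudes from a breathing-paced behavioral
    task, and the binary task responses themselves into a posterior
    distribution of the instantaneous probability of wakefulness, estimated
    with a particle filter over latent random-walk states and slowly walked
    observation coefficients. Includes multitaper spectrogram estimation and
    EMG envelope preprocessing, breath-trial scoring rules, Bayesian Monte
    Carlo goodness-of-fit comparison against hypnogram-derived instantaneous
    transition models, wake-probability-aligned population spectrograms with
    bootstrap group comparison, and a synthetic-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
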