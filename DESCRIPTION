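Package: icdyn
Title: Signal Manifolds and Latent Dynamics of Auditory Midbrain Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sensorineural hearing loss distorts the
    low-dimensional, trial-reproducible ("signal") component of auditory
    midbrain population activity. Provides calibrated auditory stimulus
    synthesis (tones, sinusoidally amplitude-modulated noise, narrowband
    target/masker pairs, synthetic consonant tokens and multi-talker babble),
    a ten-channel wide-dynamic-range-compression hearing-aid simulator, a
    synthetic inferior-colliculus population generator with ground-truth
    latent dynamics, multi-unit activity extraction and auditory-brainstem-
    response thresholding, PCA-based signal-manifold identification with
    signal/noise variance decomposition, a bottlenecked convolutional
    encoder of neural activity trained by Poisson regression, and latent-
    dynamics comparison via representational similarity analysis, (multiway)
    canonical correlation alignment, and consonant decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
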