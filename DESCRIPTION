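Package: opmclean
Title: Automatic Physiological Artifact Removal for Wearable OPM-MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognition and removal of ocular (blink) and cardiac physiological
    artifacts in optically-pumped-magnetometer magnetoencephalography (OPM-MEG)
    recordings. Independent components of band-passed 10-s epochs are scored
    against dedicated ocular and cardiac magnetic reference channels with the
    randomized dependence coefficient (copula transform, random sinusoidal
    features, regularized canonical correlation), thresholded into a labeled
    training corpus, and classified by a channel-attention 1-D convolutional
    network (CA-SeqNet) so that artifact components can be excluded during ICA
    reconstruction without reference channels at deployment time. Includes a
    ground-truthed synthetic session generator (neural background, blink and
    QRS-like cardiac trains, auditory evoked responses), evaluation metrics,
    event-related field averaging, and pre/post-stimulus SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
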