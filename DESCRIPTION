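Package: harpipe
Title: Wearable-Sensor Human Activity Recognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a human-activity-recognition
    pipeline for body-worn inertial sensors: mode-integrated binning for data
    cleaning, entropy-guided k-means discretization, a Haar/Symlet wavelet
    scattering front end for feature extraction, wrapper feature selection by a
    binomial-step Golden Eagle optimizer, scatter-matrix feature normalization,
    and a shared-filter (Lego) neural classifier trained by explicit-Euler
    gradient descent, evaluated with accuracy, precision, recall and F-score
    under a stratified 80/20 split. A seeded synthetic-data generator emulates
    class-conditional oscillatory sensor streams with injected missing,
    duplicated and corrupted records so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
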