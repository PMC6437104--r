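Package: laughdx
Title: Depression Screening from the Acoustic Structure of Laughter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for screening depression from laughter
    recordings. Laughter bouts are segmented into their elementary energy
    bursts (plosives), six acoustic variables are measured on each burst
    (duration, mean fundamental frequency, the first three formants, average
    power, spectral Shannon entropy, and the voiced fraction), and small
    neural-network classifiers (multilayer perceptrons and a hybrid radial
    basis function network trained from scratch) discriminate patients from
    controls. A seeded source-filter simulator generates laughter audio with
    controllable class differences in entropy, energy and fundamental
    frequency arch, providing ground truth for every stage. The evaluation
    battery covers confusion matrices, validity metrics, MSE/NMSE/correlation,
    AIC and MDL model selection, ROC curves and input-sensitivity ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
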