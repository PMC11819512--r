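Package: porpoisesocial
Title: Classification and Temporal Modelling of Harbour Porpoise Social Click Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying social acoustic behaviour of
    harbour porpoises from passive acoustic monitoring click-train records.
    Simulates truth-labelled narrow-band high-frequency (NBHF) click-train
    deployments with diel and seasonal encounter structure, filters candidate
    trains by mean click rate and centroid frequency, classifies social versus
    non-social trains by explicit rate-profile criteria (discreteness,
    repetition, 200-1000 clicks/s band, absence of searching phase and feeding
    buzz), aggregates detection-positive minutes (DPM) per hour, and models
    temporal structure with negative-binomial generalized additive models with
    cyclic smooths and AR1 residual correlation, alongside Kruskal-Wallis and
    Dunn-Bonferroni tests on social-DPM proportions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
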