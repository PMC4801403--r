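Package: cachalot
Title: Passive-Acoustic Line-Transect Abundance of Sperm Whales with
    Availability-Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating sperm whale density and abundance from
    towed-hydrophone line-transect surveys. Implements bearing-crossing
    localization of clicking whales with port/starboard disambiguation,
    maximum-likelihood fitting of hazard-rate and half-normal detection
    functions with AIC selection and effective strip half-width (ESHW)
    estimation, a Monte Carlo alternating-renewal model of acoustic
    availability that yields the track-line detection probability g(0)
    from bio-logging dive and vocalisation records, and the downstream
    density, abundance, coefficient-of-variation and log-normal interval
    chain, ending in a sustainability check of anthropogenic mortality
    against the stock's maximum rate of increase. A synthetic-data module
    simulates stereotyped sperm-whale dive cycles and whole survey
    scenarios for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
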