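Package: impactwave
Title: Wavelet-Packet Frequency-Response Analysis of Blunt Head Impacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frequency-domain analysis of head acceleration signals from
    blunt impacts. Implements a full wavelet packet decomposition (Symlet-2
    filter bank, periodized boundary handling) with frequency-ordered
    sub-band energies, three frequency-domain injury indicators (peak
    sub-band energy, its band position and its share of the total signal
    energy), the Head Injury Criterion (HIC), a lumped-parameter
    block-skull-brain impact simulator covering a full factorial design of
    impactor position, material, velocity and size, and the downstream
    statistics (min-max normalization, Kruskal-Wallis factor tests and
    linear regression with R squared).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
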