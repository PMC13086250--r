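Package: dyadtune
Title: Dyadic fNIRS Hyperscanning Analysis with Generative Musical Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how consonant chord progressions and live face
    gaze modulate dyadic neural activity with functional near-infrared
    spectroscopy (fNIRS) hyperscanning. Procedurally composes ii-V-I-vi
    chord-progression stimuli and note-shuffled controls and renders them to
    audio; extracts rhythm and timbre features (fluctuation spectrum, pulse
    clarity, spectral flux, centroid); simulates dyadic three-wavelength
    optical-density recordings with known ground truth; preprocesses via
    Beer-Lambert inversion, wavelet detrending and a PCA spatial global mean
    filter; fits block-design GLMs with a canonical double-gamma HRF; computes
    cross-brain wavelet coherence with a scrambled-pair null; and analyses
    connectedness ratings with Kruskal-Wallis, Games-Howell and Bonferroni
    pairwise tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
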