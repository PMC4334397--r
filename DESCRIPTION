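Package: ericfot
Title: Forced Oscillation Technique Impedance Analysis with the Extended RIC Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis chain for the forced oscillation technique (FOT):
    spectral estimation of respiratory impedance from pressure/flow
    recordings with coherence-based exam quality control, the standard
    resistive and reactive oscillometry indices (R0, S, R4, fr, Xm, Ax,
    Cdyn, Zrs4), and Levenberg-Marquardt fitting of the extended RIC
    (eRIC) equivalent circuit (central resistance, peripheral resistance,
    inertance, alveolar compliance). Includes a virtual-subject generator
    that synthesizes pseudorandom-noise FOT exams from eRIC loads under
    named cohort profiles (control, cystic fibrosis), a two-group
    statistics layer with a Shapiro-Wilk normality gate, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
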