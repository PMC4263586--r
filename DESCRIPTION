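Package: rtcatox
Title: Impedance-Based Real-Time Cell Analysis for Toxicology Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for impedance-based real-time cell analysis
    (RTCA) experiments on electrode-bearing 96-well plates. Computes the
    cell index from electrode resistance spectra, normalizes cell-index
    traces to the last point before compound addition, classifies
    time-dependent cell response profiles into mechanism-of-action classes
    (calcium modulator, antimitotic, DNA damaging, nuclear receptor) with
    explicit quantitative shape rules, applies a genotoxicity decision rule
    with sensitivity/specificity/concordance evaluation, and performs
    endpoint cytotoxicity analysis (percent viability, cross-readout
    correlation, LC50 by bracketing linear regression). Includes a seeded
    synthetic plate-experiment generator emulating the characteristic
    response archetypes of each mechanism class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
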