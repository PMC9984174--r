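Package: jnknoise
Title: Single-Cell Heterogeneity of Apoptotic JNK Signaling from Gene
    Expression Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble simulation and single-cell analysis of the
    stress-activated JNK kinase cascade in neuroblastoma. Provides a
    deterministic ODE model of the three-tiered ZAK-MKK4/7-JNK network with
    a switchable JNK-to-MKK7 positive feedback and Akt inhibitory
    cross-talk, parameterized per cell by relative protein abundances;
    kinase-translocation-reporter (KTR) conversion between
    cytoplasmic:nuclear ratios and active-kinase concentrations;
    longitudinal single-cell trace quality control, caspase-onset calling
    and apoptotic-threshold statistics; an effect-size-gated statistics
    layer for large single-cell samples; and synthetic-data generators that
    emulate five-color flow cytometry tables and live-cell biosensor
    traces so the whole pipeline is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
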