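Package: nfkbswitch
Title: Digital NF-kB Activation Under Dose- and Duration-Modulated Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic single-cell modelling and trajectory analysis of
    switch-like (digital) NF-kB activation. Provides a deterministic per-cell
    ODE model of the IKK-IkBa-A20 core module with an LPS receptor layer
    (TLR4/TRAF6, cooperative IKK activation via Hill kinetics) and a TNF
    variant; lognormal extrinsic-noise population sampling; dose by duration
    stimulation screens in sealed or perfused chamber modes; trajectory
    feature extraction (activation calls, first-peak timing, amplitude and
    baseline-corrected area, heterogeneity statistics, Hill dose-response
    fits, pairwise t-tests); the integrate-and-threshold "Area Rule"
    reduction relating stimulus integral (concentration x duration) to the
    fraction of activating cells; and a synthetic microscopy-track generator
    with ground truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
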