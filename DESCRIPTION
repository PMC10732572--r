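Package: bindassay
Title: Models and Fitters for Multi-Site Binding, Biosensor and Stability Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models for characterising cation-regulated
    protein-protein interactions of EF-hand calcium sensors: an exact solver
    for the stoichiometric sequential three-site binding equilibrium with an
    isothermal titration calorimetry (ITC) forward model and nonlinear
    fitter; 1:1 saturation models for fluorescence titrations and biolayer
    interferometry (BLI) sensograms; exponential progress-curve analysis of
    guanine-nucleotide exchange with a one-site calcium-activation
    hyperbola; two-state nano-DSF melt-curve modelling with first-derivative
    inflection-temperature detection; and a structure interface analyzer
    (contacts, hydrogen bonds, buried surface area).  Synthetic-data
    generators with known ground truth make every fitting stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
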