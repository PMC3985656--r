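Package: g4ionx
Title: Cation-Exchange Equilibria, Kinetics and Topology of G-Quadruplex
    NMR and CD Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of monovalent-cation exchange in DNA
    G-quadruplexes from solution NMR and circular dichroism data. Implements
    the three-state stepwise Na+/K+ exchange isotherm (pure Na+ form, mixed
    di-cation intermediate, pure K+ form) with per-residue fitting of the two
    stepwise equilibrium constants from imino-proton titration series;
    mono- and bi-exponential fitting of hydrogen-deuterium exchange,
    hybridization-trap and real-time CD conversion traces; inter-proton
    distance calibration from NOESY buildup initial slopes against the
    thymine H6-CH3 reference; rule-based G-quadruplex topology inference
    (tetrad detection from imino-aromatic NOE connectivity, glycosidic
    syn/anti calls, strand orientations, loop taxonomy, fold label); and
    melting-temperature extraction from the derivative of CD melting curves.
    A synthetic-data module generates every input the pipeline consumes,
    including Tel23 scenario presets, so all stages run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    methods
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Metabolomics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
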