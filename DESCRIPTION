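Package: stabevol
Title: Stability-Constrained Codon Evolution and Site-Specific Propensity Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates protein-coding sequence evolution under a thermodynamic
    mutation-selection model in which fitness equals the probability of folding
    into a native contact structure. Provides contact-map construction from PDB
    structures or synthetic compact chains, contact-potential energetics with a
    Gaussian unfolded-state ensemble, an HKY85 origin-fixation jump chain,
    site-specific amino acid fitness and propensity landscapes, residency-window
    shift metrics (slope-of-linear-regression and average-minus-initial),
    landscape-entropy analyses of stabilizing and destabilizing substitutions,
    and randomized and autocorrelated null models for metric calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    bio3d,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
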