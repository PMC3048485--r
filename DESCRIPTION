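Package: rbpmoments
Title: Low-Resolution Electric Moments of RNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes net charge, dipole moment and quadrupole-tensor
    eigenvalues of protein chains from alpha-carbon coordinates alone,
    using a unit-charge scheme (Lys/Arg +1, Asp/Glu -1, His optionally
    +1). Provides bound/unbound structure-pair comparison via a
    root-mean-square Euclidean distance, within-cluster conservation
    (noise-to-signal) ratios, group-difference t-tests, and a small
    feed-forward neural classifier with leave-one-out jackknife
    evaluation, ROC/AUC and best-F-measure reporting, for discriminating
    RNA-binding protein classes. Includes a synthetic-fixture generator
    (point-charge structures with analytic moments, perturbed structure
    pairs, Gaussian feature tables) and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
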