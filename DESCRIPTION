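Package: glomap
Title: Spatial Transcriptomic Reconstruction of Olfactory Receptor Glomerular Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers three-dimensional positions of olfactory receptor (OR) and
    trace amine-associated receptor (TAAR) glomeruli on the olfactory bulb
    surface from serial-section bulk RNA-seq along the anteroposterior,
    dorsoventral and mediolateral axes. Provides OMP-based section weighting
    and min-max normalization, expression-weighted mean axis positions and
    group-level positional statistics, a Bayesian multinomial-Dirichlet
    composition model projected onto a voxel surface scaffold with
    mirror-symmetric glomerulus pair assignment, and analyses linking OR
    protein sequence to glomerular position (pairwise percent identity,
    Grantham-distance residue permutation tests, gradient-boosted position
    regression). A synthetic sectioning-experiment generator with planted
    ground truth makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
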