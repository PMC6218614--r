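Package: cloreta
Title: Cortical LORETA Source Reconstruction with Discrete
    Laplace-Beltrami Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distributed EEG source reconstruction on triangulated
    cortical surfaces using the l2-regularized LORETA inverse with a
    cortical constraint.  Implements four discrete Laplace-Beltrami
    operators (unweighted and weighted graph Laplacians, unweighted and
    mixed-area-weighted cotangent Laplacians) as spatial smoothness
    priors, depth weighting, direct and truncated-SVD inverse operators,
    the SVD-cutoff-index procedure for choosing the regularization
    parameter, and a simulation benchmark with localization-error,
    depth-shift, residual-variance and local-maxima measures.  Includes
    synthetic generators for icosphere and corrugated cortex-like
    surfaces, quasi-equidistant spherical electrode montages, and an
    analytic homogeneous-sphere leadfield, plus readers and writers for
    OFF, ASCII PLY and plain-text mesh formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
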