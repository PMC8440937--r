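Package: aortacohort
Title: Virtual Patient Cohort Generation for Thoracic Aorta Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building statistical shape models of thoracic-aorta-like
    tubular anatomies and generating virtual patient cohorts from them. The
    package parameterizes a triangulated aortic surface as a cubic B-spline
    centerline plus a periodic wall-radius model, builds a PCA shape space over
    the parameterization coefficients, draws new anatomies with bootstrap,
    multivariate Gaussian, uniform and generative-adversarial-network samplers,
    and screens candidates with data-driven (range, two-sigma, unimodal
    Chebyshev) and clinically-driven (aortic-root phenotype) acceptance
    criteria. Support-vector-machine surrogates of the acceptance functions
    accelerate screening when biomarker evaluation is expensive. A procedural
    generator of arch-shaped synthetic aortas with known ground truth supports
    testing and end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    e1071,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
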