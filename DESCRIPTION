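Package: tomopt
Title: Modular Optimization Framework for Tomographic Image Reconstruction
Version: 0.1.0
Authors@R:
    person("Core", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for tomographic image reconstruction
    formulated as convex optimization.  Provides labelled data containers
    tied to acquisition and image geometries, preprocessing processors
    (normalisation, negative-log conversion, slicing, binning, padding,
    centre-of-rotation estimation, masking), a linear-operator calculus with
    direct/adjoint contracts including a native ray-driven parallel-beam
    projector with matched back-projector, a convex-function calculus with
    gradients, proximal mappings and convex conjugates (least squares, L1,
    mixed L2,1, smoothed L2,1, Kullback-Leibler, box indicators, total
    variation via fast gradient projection), iterative solvers with
    resumable state (CGLS, SIRT, gradient descent, FISTA, PDHG), a filtered
    back-projection baseline, and a phantom/noise simulator with quality
    metrics, TIFF-stack and HDF5 input/output and a YAML-driven command-line
    interface.  All functionality is exercised on synthetic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
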