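Package: sphereg
Title: Sphere-Fiducial Scene Registration for Surgical Vision Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers a scanned surface mesh of a surgical scene to a set of
    calibrated camera viewpoints using spherical fiducial markers. Spheres of
    known radius are localized in the mesh by fixed-radius iterative sphere
    fitting, their elliptical projections are detected in images and fitted as
    conics, and the mesh-to-world rigid (or similarity) transform is recovered
    by exhaustive Perspective-n-Point correspondence search followed by
    Levenberg-Marquardt minimization of the conic bilinear residual. Includes
    the accompanying accuracy metrics (radial error of back-projected outline
    rays, ellipse reprojection error, Chamfer distance between meshes), a
    synthetic-scene simulator with ground truth for end-to-end validation,
    COLMAP text-model and robot-pose input handling, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    png,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'camera.R'
    'io-images.R'
    'io-colmap.R'
    'io-mesh.R'
    'conics.R'
    'synthetic-scene.R'
    'ellipse-fit.R'
    'transforms.R'
    'registration-init.R'
    'registration-refine.R'
    'registration.R'
    'cli.R'
    'ellipse-detect.R'
    'evaluation.R'
    'render.R'
    'sphere-fit.R'
    'sphereg-package.R'
    'utils-rotation.R'
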