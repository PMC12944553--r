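Package: vacp
Title: Video-Acoustic Clinical Phenotyping of Facial Motor Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for grading the severity of post-stroke facial motor
    impairment (dysarthria with central facial paralysis) from facial video
    and speech. Provides frame-level exposure and occlusion quality control,
    68-point landmark alignment with angular verification, motion-amplitude
    keyframe (apex) annotation against a neutral reference, an SVR/SVM facial
    action unit estimator over HOG and geometric features, Delaunay-triangulated
    multi-region landmark graphs embedded by a graph convolutional encoder,
    an 88-functional acoustic feature contract, and a compact fused deep
    network classifier evaluated by repeated stratified splits. A seeded
    synthetic cohort generator with known ground truth (apex frames, action
    unit drives, class labels) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
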