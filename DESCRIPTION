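Package: mandigrow
Title: Longitudinal 3D Morphometrics of Mandibular Growth from Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring long-term three-dimensional mandibular growth
    from triangle surface meshes, as produced by segmenting serial cone-beam CT
    scans. Provides geometric primitives (watertight mesh volume, discrete
    curvature, extremal queries, supporting planes, plane bisection and
    plane-surface intersection), automatic detection of anatomical landmarks
    (condylar poles, coronoid process, genial tubercle, and the gonion via a
    three-plane tangent construction), ingestion of manually placed landmarks
    with repeatability assessment (intraclass correlation), an inventory of
    inter-marker distances in four orientation groups plus inter-segmental
    angles and bone volume, and longitudinal growth statistics (monthly change,
    normalized total change, percent-of-change, repeated-measures ANOVA across
    orientation groups with Bonferroni-corrected pairwise tests). A synthetic
    generator of anisotropically growing, bilaterally near-symmetric
    mandible-like meshes with known ground-truth landmark trajectories supports
    validation and end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
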