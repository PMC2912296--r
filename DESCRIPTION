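Package: tstkit
Title: Tissue Surface Tensiometry Analysis of Cell Aggregate Cohesion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for parallel-plate tissue surface tensiometry
    of 3D cell aggregates. Converts equilibrium compression force and profile
    geometry into apparent surface tension via the Young-Laplace relation,
    discriminates viscoelastic-liquid from elastic-solid aggregates by
    comparing surface-tension ratios to force ratios across two successive
    compressions, and summarizes cohorts of aggregates across receptor
    expression clones and soluble-fibronectin conditions. Includes kinetic
    analysis of aggregate compaction and ligand depletion time courses,
    skeleton-based fiber morphometry of fluorescence images, and seeded
    synthetic-data generators (compression records, compaction/depletion
    trajectories, fiber images with ground truth) so the whole chain is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
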