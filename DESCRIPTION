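Package: looprule
Title: Loop Length Estimation Along Cryo-EM Density-Map Skeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the length of the loop connecting two alpha-helices in a
    medium-resolution (5-10 Angstrom) cryo-EM density map, measured along a
    voxel skeleton of the map. Skeleton voxels inside the helix regions are
    masked away using the detected helix central axes, the remaining voxels are
    clustered into local connectivity graphs, the cluster nearest each
    helix-endpoint pair is selected by directed Hausdorff distance, a
    breadth-first-search path is traced between the endpoints, and the path is
    simplified with Douglas-Peucker vertex removal before its length is
    measured and compared with the sequence-based expectation of
    3.8 Angstrom x (n + 1) for a loop of n residues. Includes readers and
    writers for MRC/CCP4 skeleton maps, plain-text point clouds and helix-axis
    annotations, and a seeded synthetic helix-loop-helix skeleton generator
    with analytically known loop lengths for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
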