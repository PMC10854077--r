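Package: marrowflow
Title: Load-Induced Marrow Flow and Fluid Shear Stress in Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static fluid-solid coupled simulation of bone marrow flow in
    trabecular (cancellous) bone under cyclic compressive loading. Provides a
    Gaussian-random-field generator for synthetic trabecular voxel geometries at
    prescribed bone volume fractions, a voxel (hexahedral) micro-finite-element
    linear elasticity solver, a staggered-grid (MAC) incompressible Stokes solver
    for the marrow phase driven by moving trabecular walls and open-boundary
    pressures, wall fluid-shear-stress (FSS) extraction at the bone-marrow
    interface, postprocessing of field statistics (central crops, section slices,
    FSS band proportions, time-in-band fractions), and nonparametric comparison
    of FSS summaries across experimental groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
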