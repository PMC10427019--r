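Package: mlfit
Title: Maximum-Likelihood Density-Guided Refinement of Atomic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for refining atomic models into cryo-EM style density
    maps with a maximum-likelihood formulation.  Provides a Gaussian
    forward model from atom coordinates to a voxel grid, four map
    similarity potentials (inner product, cross-correlation, and two
    relative-entropy scores derived from Dirichlet and Poisson noise
    models), analytic biasing forces, an adaptive force-constant scaling
    protocol with exerted-work accounting, a toy Brownian-dynamics engine
    for model studies (effective landscapes, mean first-passage-time
    benchmarks, bead-helix refinement), and scoring tools (Fourier shell
    correlation, superposition-free RMSD).  Reads and writes MRC/CCP4
    volumes and PDB coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
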