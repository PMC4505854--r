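Package: gbmsim
Title: Diffuse-Interface Mixture Model of Glioblastoma Growth with
    Fiber-Guided Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates glioblastoma multiforme invasion as an incompressible
    binary mixture of tumor cells and host tissue with a diffuse interface.
    The tumor phase obeys a fourth-order Cahn-Hilliard-type equation with
    degenerate mobility, adhesion/repulsion bulk energy and a Keller-Segel
    chemotactic flux biased along white-matter fiber directions; oxygen obeys
    an anisotropic reaction-diffusion equation. The fiber bias enters through
    a tensor of preferential directions obtained by normalizing a diffusion
    tensor field (for example from diffusion tensor imaging) by its mean
    diffusivity. The package provides the constitutive laws, synthetic tensor
    phantoms and NIfTI tensor-volume input, structured tetrahedral meshes with
    local red-green refinement, a mixed P1 finite-element solver with
    Crank-Nicolson time stepping, tumor-shape metrics, and drivers for
    parameter-sensitivity sweeps and anisotropic-versus-isotropic growth
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'gbmsim-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mesh.R'
    'mesh-io.R'
    'toml.R'
    'metrics.R'
    'tensor-field.R'
    'model-core.R'
    'fem.R'
    'solver.R'
    'experiments.R'
    'cli.R'
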