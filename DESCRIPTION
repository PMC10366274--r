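Package: vertebropm
Title: Continuum Porous-Media Simulation of Bone-Cement Injection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Macro-scale multiphase model of bone-cement injection into a
    porous medium (vertebroplasty), built on the Theory of Porous Media: an
    elastic solid skeleton plus two immiscible pore fluids (shear-thinning
    cement and bone marrow) sharing one pore pressure. Pore-scale rheology
    follows the Carreau model with Brooks-Corey relative permeabilities, and
    three interchangeable viscosity-upscaling models (Cannella,
    Hirasaki-Pope, and a semi-analytical average-viscosity model) map it to
    the macro scale. The coupled balance equations are discretized on
    trilinear hexahedra with a vertex-centered finite-volume Box scheme
    (fully-upwind mobilities, mass-lumped storage, implicit Euler) for the
    fluids and Bubnov-Galerkin finite elements for the solid, and solved
    monolithically by Newton's method. Includes generalized-Newtonian tube
    flow for rheology identification from injection data, ready-made
    benchmark and clinical scenarios, parameter sweeps, VTK field output,
    and tidy result accessors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
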