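Package: bendscape
Title: Free-Energy and Geometry Analysis of Tubulin Straight-Bent
    Conformational Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for studying the straight-bent
    conformational equilibrium of the alpha/beta-tubulin heterodimer.
    Provides structure-based curvature metrics (intradimer rotation from
    least-squares planes through the H7 helices, intramonomer
    intermediate-domain rotations, domain center-of-mass bending angles,
    buried surface area by Shrake-Rupley sampling, van der Waals steric
    clashes), path collective variables s(R)/z(R) over linear morph paths,
    umbrella sampling on analytic free-energy landscapes with an
    overdamped-Langevin integrator, the weighted histogram analysis method
    (WHAM) in one and two dimensions with bootstrap uncertainty, basin
    population thermodynamics, and a two-step nucleation-elongation model
    of microtubule assembly with a conformational straightening penalty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
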