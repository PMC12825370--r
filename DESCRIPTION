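Package: monofilm
Title: Slab-Model X-Ray Reflectivity and Composition Analysis of
    Surfactant Films at the Air-Water Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of specular X-ray reflectivity from surfactant films at
    the air-water interface. Represents the interfacial electron-density
    profile as a stack of error-function-smoothed slabs, computes specular
    reflectivity by the Parratt recursion with Nevot-Croce roughness damping
    (with a fine-slicing fallback for rough thin layers), normalizes to the
    Fresnel reflectivity of the ideal interface, and fits slab parameters by
    bounded least squares followed by affine-invariant ensemble MCMC with
    84 percent credible-interval uncertainty reporting. Fitted slabs are
    converted into monolayer composition (area per molecule, surface
    excesses, waters per headgroup) through per-slab electron-balance
    equations, with a molar-volume balance reported as a consistency check.
    Equilibrium surface tension versus bulk concentration is fitted to the
    Langmuir/Szyszkowski isotherm, and the critical micelle concentration is
    located as a piecewise-linear plateau breakpoint. A synthetic-data module
    generates reflectivity curves, tension isotherms, and relaxation traces
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
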