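Package: mcuflux
Title: Biophysical Models of the Mitochondrial Calcium Uniporter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux models of the mitochondrial Ca2+ uniporter: an Eyring
    free-energy-barrier formulation with constant barrier-displacement
    parameters, and a generalized nonlinear Goldman-Hodgkin-Katz (GHK)
    formulation in which the barrier parameters become smooth analytic
    functions of membrane potential governed by a single shape parameter.
    Includes the kinetic and thermodynamic constraints linking the
    parameters, synthetic generation of the classical Ca2+-titration and
    membrane-potential-titration uptake protocols, a staged constrained
    least-squares parameter-estimation pipeline with multistart, and
    sensitivity/identifiability diagnostics (matrix-Ca2+ robustness
    envelopes, potential/concentration sweep families, barrier-parameter
    curves, and the Case-2 scaling non-identifiability family).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
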