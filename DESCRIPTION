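Package: tcskinetics
Title: Kinetic Models of Reciprocal Regulation in Bifunctional Two-Component Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mass-action models of bacterial two-component signaling with a
    bifunctional sensor kinase whose autokinase and phosphatase activities are
    reciprocally regulated by an allosteric effector, together with the related
    covalent modification cycle driven by a bifunctional converter enzyme.
    Provides stiff ODE steady-state solvers, algebraic steady-state reductions
    (Batchelor-Goulian quadratic, Goldbeter-Koshland form, low- and
    high-affinity limits), ultrasensitivity and concentration-robustness
    diagnostics (effective Hill coefficients, plateau/threshold reports),
    least-squares fitting workflows for titration data, and a synthetic-data
    generator for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, jsonlite, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
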