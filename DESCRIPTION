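Package: tgfsmad
Title: Mass-Action ODE Models of TGF-beta/Smad Negative Regulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A family of compartmental mass-action ordinary differential
    equation models of TGF-beta/Smad signalling in HaCaT keratinocytes,
    with alternative negative-regulation mechanisms (R-Smad
    dephosphorylation, Smad7-driven receptor degradation, proteasomal
    P-Smad degradation, endogenous R-Smad turnover, inhibitory-Smad
    feedback, and PPM1A upregulation by expression or PTEN-mediated
    stabilization).  Provides stimulation and perturbation protocols
    (ligand washout with receptor-kinase inhibition, proteasome
    inhibition, cycloheximide), multistart least-squares parameter
    estimation with a model-rejection workflow, in-silico experiments
    (receptor-degradation rate sweeps, proteasome-inhibition
    reconciliation, sensitivity maps, dose response, effect-contribution
    decomposition), a synthetic time-course generator for recovery and
    rejection studies, and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
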