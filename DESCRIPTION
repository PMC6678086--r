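Package: domainmotion
Title: Domain Motion Analysis for Biomolecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies relative motions of quasi-rigid protein domains in
    molecular dynamics trajectories. Builds per-frame local coordinate
    systems from the principal axes of each domain's C-alpha cloud,
    standardizes eigenvector orientation against a crystal reference,
    and derives inter-domain distance and orientation-angle time series,
    RMSD/RMSF deformation statistics, and bound-versus-free ensemble
    comparisons via the two-sample Kolmogorov-Smirnov statistic. Includes
    a synthetic rigid-body trajectory generator with recorded ground
    truth for closed-loop validation, multi-model PDB input/output, and a
    config-driven analysis pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
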