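Package: eeftraj
Title: Trajectory Analysis of Tubulin Dimers in External Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of an alpha/beta
    tubulin heterodimer exposed to static external electric fields.
    Implements the observables used to characterise the field response:
    RMSD time series split by secondary-structure class, per-residue RMSF
    and field-minus-ambient delta-RMSF, endpoint "final displacement" after
    optimal superposition, fixed-charge dipole moments, intradimer bend
    angle from best-fit helix axes, monomer elongation, charged-loop
    distance distributions, salt-bridge detection, and mean squared
    displacement. Includes a synthetic-trajectory generator with known
    ground truth (rigid helical cores, charged flexible loops with
    field-coupled mean shifts, Ornstein-Uhlenbeck positional noise,
    frame-wise bend and elongation draws, Brownian drift) so every stage is
    verifiable without running molecular dynamics, plus a pipeline driver
    that runs all stages over a condition matrix from one configuration.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
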