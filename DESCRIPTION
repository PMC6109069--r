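Package: hkadyn
Title: Dynamic pKa Correlation, Proton-Transfer Networks and Binding
    Free-Energy Analysis for P-Type ATPase Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics ensembles of the
    gastric H+,K+-ATPase cation-binding pocket in the luminal-open E2P
    state. Enumerates the protonation microstates of the five-carboxylate
    binding pocket, ingests or estimates per-frame pKa time series for the
    titratable residues, computes windowed Pearson correlation matrices
    with Fisher-z confidence intervals, infers directed proton-transfer
    networks from strongly anti-correlated donor/acceptor pairs, derives
    spontaneous K+ binding-site occupancy statistics from trajectory
    frames, and computes 1-D umbrella-sampling potentials of mean force by
    the weighted histogram analysis method (WHAM) with block-bootstrap
    errors. A synthetic-data module generates statistically faithful
    stand-in inputs (correlated AR(1) pKa series, stochastic ion-binding
    trajectories, Boltzmann-sampled umbrella windows) so the whole
    pipeline is testable without trajectory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
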