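Package: stardynet
Title: Trajectory Analysis, Allosteric Networks and Umbrella-Sampling Free
    Energies for Protein-RNA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for molecular-dynamics ensembles of
    protein-RNA complexes such as the STAR (KH-QUA2) domain bound to its
    mRNA target.  Provides deviation and fluctuation statistics (RMSD,
    RMSF, B-factor conversion, running-average convergence curves),
    native-contact metrics (Q and Gaussian-penalised Qs), contact counts
    and interface occupancies, solvent-accessible surface area,
    dynamic cross-correlation maps and principal component analysis,
    correlation-weighted dynamical network analysis (Floyd-Warshall
    shortest paths, characteristic path length, Girvan-Newman
    communities, node/edge-removal perturbation scans), 1D/2D weighted
    histogram analysis (WHAM) reconstruction of umbrella-sampling
    potentials of mean force with bootstrap errors, and RNA backbone
    geometry (sugar pseudorotation, eta/theta pseudo-torsions).  A
    synthetic-data module generates harmonic ensembles with planted
    covariance, Metropolis-sampled umbrella windows from analytic
    potentials, and a toy protein-RNA complex so that every stage is
    verifiable against closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
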