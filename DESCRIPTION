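Package: resFEP
Title: Hybrid-Topology Free Energy Perturbation Toolkit for Protein Point Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Setup and analysis toolkit for alchemical free energy
    perturbation (FEP) calculations of amino-acid point mutations using a
    hybrid (dual-like) topology: a shared backbone with separate,
    mutually non-interacting wild-type and mutant side chains. Provides
    PDB-based spherical-system bookkeeping, a residue template library
    with internal-coordinate side-chain construction, analogous-atom
    mapping with an automated pairwise distance-restraint scheme,
    two-stage lambda-window protocols with sampling budgets, Zwanzig and
    Bennett acceptance ratio (BAR) free-energy estimators with replica
    averaging and thermodynamic-cycle solving, systematic mutation-scan
    enumeration, benchmark figures of merit with bootstrap confidence
    intervals, and a one-dimensional harmonic toy sampler with
    closed-form free energies for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
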