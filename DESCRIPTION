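Package: polyphonon
Title: Rigid-Body Quasi-Harmonic Lattice Dynamics for Molecular Crystal
    Polymorphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rigid-body harmonic and quasi-harmonic lattice dynamics for
    molecular crystals: exp-6 atom-atom lattice energies with point-charge
    Ewald electrostatics, rigid-body phonon spectra with a Debye treatment
    of the acoustic branches and kernel-density smoothing of the optic
    density of states, vibrational free energies and entropies, thermal
    expansion by the thermal-pressure method, elastic tensors with
    Voigt-Reuss-Hill aggregate moduli and their temperature softening,
    melting-point estimators, and pairwise polymorph free-energy re-ranking
    with enantiotropic/monotropic classification. Includes deterministic
    toy-crystal generators with analytic oracles and a command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
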