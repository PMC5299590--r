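# polyphonon

Rigid-body harmonic and quasi-harmonic lattice dynamics for molecular
crystal polymorphs, in R.

Polymorphs of an organic molecule — distinct crystal packings of the same
compound — usually differ in lattice energy by only a few kJ mol⁻¹, so
their relative stability can flip with temperature. Whether it does is
decided by lattice vibrations: the vibrational free energy and entropy of
each packing, and their change as the crystal thermally expands.
`polyphonon` implements the full chain needed to rank polymorphs as a
function of temperature with a rigid-molecule atom–atom force field:

* **Lattice energy** — exp-6 (Buckingham) repulsion–dispersion summed
  between whole molecules within a centre-of-mass cutoff (default 20 Å),
  plus point-charge electrostatics by Ewald summation,
  `E_inter = Σ [A·exp(−B·R) − C/R⁶] + E_elec`.
* **Structure relaxation** — quasi-Newton minimization of
  `E_inter + P·V` over the 6 cell parameters and the rigid-body
  translations and rotations of every molecule, at any external pressure.
* **Phonons** — analytic rigid-body dynamical matrices at arbitrary
  wavevector (translations mass-weighted by molecular mass, librations by
  the principal moments of inertia), uniform Brillouin-zone sampling, a
  Debye model for the acoustic branches and a Gaussian-KDE density of
  states for the optic branches; vibrational free energy `F_vib(T)`,
  analytic entropy and heat capacity, `A_HA(T) = E_latt + F_vib(T)`.
* **Thermal expansion** — the thermal-pressure route to the
  quasi-harmonic approximation: `P_th(T) = −∂F_vib/∂V`, relaxation at
  `−P_th` (iterated to self-consistency), and
  `A_QHA(T) = E_latt(T) + F_vib(T)` on the expanded structure, with the
  finite-difference expansion coefficient `α_V = (V_T − V_0)/(V_0·T)`.
* **Elastic moduli** — stiffness tensors from finite Voigt strains with
  rigid-body internal relaxation, Voigt/Reuss/Hill aggregate bulk and
  shear moduli, and their softening with temperature.
* **Melting points** — the Gold–Ogle rule `T_m = 0.5839·T_b` and a
  variance-stabilized regression `T_m = β0 + β1·√(−E_inter)`, averaged.
* **Polymorph pipeline** — Kabsch conformer RMSD, pairwise
  `ΔA_QHA(0)`/`ΔA_QHA(T_m)` comparison with
  enantiotropic/monotropic/diverging classification, Hermite free-energy
  curves with analytic-entropy slopes, transition-temperature search, and
  survey statistics over many pairs.

Everything is testable offline: `chain_1d()`, `exp6_fcc()` and
`rigid_diatomic_crystal()` generate deterministic toy crystals whose
dispersion, minima, elastic constants and free-energy surfaces have
analytic or brute-force oracles (see the methods vignette in
`vignettes/`).

## Worked example

```r
library(polyphonon)

fx <- exp6_fcc()                      # argon-like exp-6 fcc test crystal
lattice_energy(fx$crystal, fx$ff)
#> E_inter   =   -34.4295 kJ/mol per molecule

sp <- sample_spectrum(fx$crystal, fx$ff, grid = c(4, 4, 4))
sp
#> phonon spectrum: 64 k-points, 12 dof/cell, Debye velocity 113.62 cm^-1 A,
#> omega_D 85.6 cm^-1
vib_free_energy(sp, 300)
#> T = 300.0 K: F_vib = -6.9981, ZPE = 1.5182, S = 0.048635, Cv = 0.024581,
#> A_HA = -41.4276 (kJ/mol per molecule)

qha_state(fx$crystal, fx$ff, 300, zpe_pressure = TRUE)
#> QHA 300 K: P_th = 0.8127 GPa, V = 39.238 A^3/molecule,
#> A_QHA = -42.3386 kJ/mol, alpha_V = 445.6 x 1e-6/K

hill_moduli(elastic_tensor(fx$crystal, fx$ff, relax_internal = FALSE))
#> K (GPa): Reuss 9.804 <= Hill 9.804 <= Voigt 9.804
#> G (GPa): Reuss 4.375 <= Hill 5.127 <= Voigt 5.880
```

Reading the output: the crystal is bound by 34.4 kJ mol⁻¹ per molecule;
its lattice modes give a 300 K vibrational free energy of −7.0 kJ mol⁻¹,
so the harmonic free energy is −41.4 kJ mol⁻¹. Letting the lattice expand
against its thermal pressure (0.81 GPa at 300 K) lowers the free energy
by a further 0.9 kJ mol⁻¹ and inflates the cell by ~13% — this fixture is
deliberately soft and strongly expansive. The Voigt and Reuss bulk-modulus
bounds coincide (~9.8 GPa) because the crystal is cubic; the shear bounds
differ and the Hill average sits between them.

For polymorph work, `compare_polymorphs()` runs the whole chain on a pair
of structures and classifies it; `rigid_diatomic_crystal(packing =
"alpha")` / `"beta"` provide a synthetic stable pair to try it on.

## Command line

A thin CLI over the same functions is installed as `exec/polyphonon`:

```sh
polyphonon convert in.cif out.cif
polyphonon optimize in.cif --ff ff.txt --pressure -0.05 --out relaxed.cif
polyphonon phonons relaxed.cif --ff ff.txt --grid 4 4 4 --temps 0,100,200,300
polyphonon qha relaxed.cif --ff ff.txt --temps 0,100,200,300
polyphonon elastic relaxed.cif --ff ff.txt
polyphonon meltfit data.csv
polyphonon compare a.cif b.cif --ff ff.txt --tm 380
polyphonon fixtures --name exp6_fcc --out dir/
```

Force fields are plain text: a `[types] label element mass charge`
section, `[pairs] type1 type2 A B C` exp-6 parameters
(kJ mol⁻¹, Å⁻¹, kJ mol⁻¹ Å⁶), an optional `[springs] type1 type2 kappa
r0 rcut` section of harmonic test potentials, and `[settings]`
(`com_cutoff`, `taper`, `ewald_accuracy`, `epsilon_r`). `#` starts a
comment. CIF I/O is core CIF 1.1, expanded to P1 on read, with custom
`_atom_site_charge` / `_atom_site_ff_type` tags.

`inst/extdata/alpha_v_benchmark.csv` ships a small benchmark table of
calculated vs experimentally determined volumetric thermal-expansion
coefficients (10⁻⁶ K⁻¹) for eight organic molecular crystals, used by
`error_stats()`.

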