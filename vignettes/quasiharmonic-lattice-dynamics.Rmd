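---
title: "Rigid-body quasi-harmonic lattice dynamics for molecular crystal polymorphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body quasi-harmonic lattice dynamics for molecular crystal polymorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polyphonon computes temperature-dependent thermodynamic and mechanical
properties of rigid-molecule crystals: lattice energies, phonon spectra,
vibrational free energies and entropies, thermal expansion, elastic
moduli, and the relative free energies of polymorph pairs. This vignette
explains the models the package implements, the choices behind the
defaults, and what its built-in test crystals do and do not demonstrate.

## The energy model

The intermolecular cohesive energy is an atom-atom sum over pairs of
rigid molecules,

$$E_\mathrm{inter} = \frac{1}{2}\sum_{M \ne N}\sum_{i \in M, k \in N}
  \left[A^{\iota\kappa} e^{-B^{\iota\kappa} R_{ik}}
  - \frac{C^{\iota\kappa}}{R_{ik}^6}\right]
  + E^\mathrm{elec},$$

where $\iota,\kappa$ are the force-field types of atoms $i,k$. The
repulsion–dispersion (exp-6) part is summed between whole molecules whose
centres of mass lie within a cutoff (default 20 Å, the convention for
atom–atom force fields of this family). Electrostatics are atomic point
charges summed by Ewald; the intramolecular Coulomb terms are subtracted
so the result is purely intermolecular. Charges beyond rank 0
(dipoles, quadrupoles, ... up to hexadecapoles) and polarizable-continuum
polarization, which the most accurate force fields of this family use,
are deliberately out of scope; the force-field container stores the
relative permittivity $\varepsilon_r$ (default 5.0) only as metadata about
how its charges were derived — it never scales an energy. This is an
accuracy caveat for absolute lattice energies; the machinery downstream of
the energy model is unaffected.

Two numerical choices matter here:

* **Cutoff taper.** A sharp centre-of-mass cutoff makes the energy
  discontinuous whenever a molecule pair crosses the boundary, which
  traps gradient-based optimizers at shell boundaries. Each molecule
  pair's short-range energy is therefore multiplied by a quintic
  smoothstep that switches from 1 to 0 over the last `taper` Ångströms
  inside the cutoff (default 1 Å; 0 restores the sharp cutoff). The
  energy and its analytic gradient include the taper exactly. In the
  phonon force constants the taper scales the pair Hessian blocks, while
  the derivative-of-taper cross terms are neglected: they involve only
  pairs at the far cutoff, where pair energies are of order
  10^-3^ kJ mol^-1^, they perturb optic frequencies by well under
  0.1 cm^-1^ on the shipped test crystals, and they cannot violate the
  acoustic sum rule.
* **Ewald splitting.** The splitting parameter is chosen from the cell
  volume and atom count; real- and reciprocal-space cutoffs follow from
  the requested accuracy (default 10^-10^ relative). Energies change by
  less than that tolerance when the splitting parameter is varied, which
  the test suite checks.

There is also a `[springs]` section in the force-field format: harmonic
pair potentials $\tfrac12\kappa(R-r_0)^2$ with a hard cutoff. These are
test potentials: they make exactly solvable crystals possible (below) and
are not part of the physical model.

## Rigid-body lattice dynamics

Molecules are treated as rigid bodies: each contributes three
translations plus one libration per principal axis with non-zero moment
of inertia (three for a non-linear molecule, two for a linear one, none
for a single atom). The dynamical matrix at wavevector $\mathbf k$ is
assembled from analytic second derivatives of the intermolecular energy:

* short-range pair Hessians summed over lattice images with phases
  $e^{i\mathbf k\cdot\mathbf R_l}$,
* the Ewald reciprocal-space contribution evaluated as a sum over
  $\mathbf K = \mathbf k + \mathbf G$,
* exact self terms fixed by translational invariance, so the acoustic sum
  rule (three zero modes at $\Gamma$) holds to machine precision,
* a librational correction coupling residual atomic forces to the
  second-order displacement of a rotating rigid body,
  $\tfrac12\,\mathbf g_i\cdot[\mathbf n_a\times(\mathbf n_b\times
  \boldsymbol\rho_i) + \mathbf n_b\times(\mathbf n_a\times
  \boldsymbol\rho_i)]$, which is essential whenever individual atoms
  carry forces at a rigid-body stationary point.

Mass weighting uses the molecular mass for translations and the principal
moments of inertia for librations. The implementation is validated in the
test suite against numerical rigid-body Hessians and against supercell
folding (the eigenvalues at $\Gamma$ and $X$ of the primitive cell must
reappear exactly at $\Gamma$ of a doubled cell — a sensitive test of the
reciprocal-space phases).

## Brillouin-zone sampling, Debye model, KDE

Frequencies are sampled on a uniform $\Gamma$-centred grid (default
4×4×4). A uniform grid was chosen over sampling by sets of linear
supercells: the sampling goal is the same and the bookkeeping is simpler.
At every k-point the three lowest branches are classified as acoustic (a
pragmatic sorting rule; branch crossings are not tracked). The acoustic
branches are represented by a Debye model: the sound velocity is fitted
on the innermost sampled k-shell as
$3/v_D^3 = \langle \sum_{j=1}^3 v_j^{-3}\rangle$, and the cutoff
frequency $\omega_D = v_D\,(6\pi^2/V)^{1/3}$ places exactly three
acoustic modes per primitive cell. All remaining (optic) branches enter
the density of states directly; a Gaussian kernel density estimate with
default bandwidth 3 cm^-1^ smooths the discrete optic frequencies into a
continuous $g(\omega)$ normalized to the optic mode count. With this
split the acoustic and optic counts add up to the full mode count with no
double counting, and the vibrational free energy converges quickly with
grid size (doubling the default grid moves $F_\mathrm{vib}(300\,\mathrm K)$
by well under 0.1 kJ mol^-1^ on the test crystals; the grid sizes used in
the tests are stated there).

Thermodynamics per mode use the standard harmonic forms; the entropy is
the analytic derivative $-\partial F/\partial T$, not a finite
difference, and the KDE integral reduces to the discrete sum as the
bandwidth goes to zero (both are available; `method = "discrete"`).

## Harmonic and quasi-harmonic free energies

$$A^\mathrm{HA}(T) = E_\mathrm{latt} + F^\mathrm{HA}_\mathrm{vib}(T),
  \qquad A^\mathrm{QHA}(0) = A^\mathrm{HA}(0) = E_\mathrm{latt} +
  \mathrm{ZPE}.$$

Thermal expansion uses the thermal-pressure method: the vibrational free
energy is differentiated with respect to volume by central differences
over isotropically scaled structures (default relative volume step
0.005), giving $P_\mathrm{th}(T) = -\partial F_\mathrm{vib}/\partial V$;
a rigid-body optimization at external pressure $-P_\mathrm{th}$ yields
the thermally expanded structure, and
$A^\mathrm{QHA}(T) = E_\mathrm{latt}(T) + F_\mathrm{vib}(T)$ is assembled
there. Two design decisions:

* **Zero-point pressure.** By default only the thermal part of
  $F_\mathrm{vib}$ enters $P_\mathrm{th}$, so $P_\mathrm{th}(0) = 0$ and
  the 0 K identity above holds exactly. The rationale: empirical force
  fields fitted to low-temperature crystal structures already contain the
  zero-point expansion implicitly, so applying the ZPE volume derivative
  on top would double-count it. `zpe_pressure = TRUE` includes it, which
  is also what the QHA-vs-oracle consistency checks use, because the
  explicit reference functional there is $E(V) + F_\mathrm{vib}(V, T)$
  with the full $F_\mathrm{vib}$.
* **Self-consistency.** $P_\mathrm{th}$ is re-evaluated at the expanded
  structure and iterated until the volume converges (relative tolerance
  2×10^-4^, usually 2–4 iterations). At the fixed point the stationarity
  condition is identical to an explicit minimization of
  $E_\mathrm{latt}(V) + F_\mathrm{vib}(V,T)$, which is how the package's
  own oracle checks verify it. A single-pass scheme (`max_scf = 1`,
  $P_\mathrm{th}$ from the 0 K reference only) is retained for
  comparison; it underestimates the expansion noticeably once
  $F_\mathrm{vib}$ is visibly curved in $V$, i.e. at strong expansion.

The volumetric expansion coefficient is reported as the finite difference
$\alpha_V = (V_T - V_0)/(V_0\,T)$ between the reference and the expanded
structure, the convention also used by the shipped benchmark table of
calculated-vs-experimental coefficients (in 10^-6^ K^-1^ units).

Structures that change drastically under the negative thermal pressure —
more than 50% volume change or a centre-of-mass displacement above 3 Å —
raise an instability error rather than returning a meaningless state, and
imaginary phonon frequencies anywhere on the grid do the same (a
diagnostic `allow_imaginary` flag reports them as negative frequencies
instead). These mirror the exclusions any large-scale survey has to make.

## Elastic moduli

The stiffness tensor comes from central second differences of the energy
density with respect to the six Voigt strains (default step 0.002,
engineering shear convention; the factor-2 bookkeeping lives in the
Voigt-to-tensor map). Energy derivatives were preferred over a stress
implementation to keep a single code path. By default the rigid-body
internal coordinates are re-relaxed at every strained cell (relaxed-ion
tensor); relaxation can only soften the tensor, and the clamped-ion
variant is available. Polycrystalline aggregates use the Voigt and Reuss
bounds and the Hill average (arithmetic mean). Temperature softening is
obtained by evaluating the tensor on the quasi-harmonically expanded
structures and reporting the percentage decrease against 0 K.

## Melting points and polymorph comparison

Melting temperatures enter only as the temperature at which polymorph
free energies are compared (one melting point per polymorph family). Two
estimators are provided: the Gold–Ogle rule $T_m = 0.5839\,T_b$, and a
regression of $T_m$ on $\sqrt{-E_\mathrm{inter}}$ — a square-root
(Anscombe) variance-stabilizing transformation; a straight
proportionality between melting points and lattice energies does not fit
real data well. The regression coefficients are fitted to the user's own
data (the package deliberately ships no fitted coefficients), and the
final estimate averages the two methods where both exist. Fragment-based
estimates (group-contribution methods) must be supplied externally.

A polymorph pair is compared by $\Delta A^\mathrm{QHA}$ at 0 K (including
ZPE) and at $T_m$: a sign change means the pair is re-ranked by
temperature and the model predicts an enantiotropic relationship;
otherwise the pair is monotropic-predicted with diverging or converging
free-energy curves depending on whether $|\Delta A|$ grows or shrinks.
Differences within a tolerance (default 0.01 kJ mol^-1^ — small compared
to any meaningful lattice-energy difference) are reported as degenerate
rather than forced into a class. Continuous free-energy curves use cubic
Hermite interpolation with the analytic entropies as slopes, so crossing
temperatures can be located by bisection. Conformer equivalence between
polymorphs is checked by Kabsch superposition RMSD, hydrogens excluded by
default, with the usual 0.25 Å packing-polymorph threshold in mind; atom
correspondence must be supplied (graph matching is out of scope).

## The built-in test crystals

Every module is exercised end to end by deterministic generators with
independent oracles:

* `chain_1d()` — a simple-cubic bead-spring crystal with zero-rest-length
  springs ($\kappa = 10$ kJ mol^-1^ Å^-2^, $m = 40$ amu, $a = 5$ Å). The
  zero rest length makes each bond an isotropic harmonic tether, which
  confines transverse motion while preserving translational invariance,
  so all three branches follow the textbook monatomic-chain dispersion
  $\omega(k) = 2\sqrt{\kappa/m}\,|\sin(ka/2)|$ exactly and the acoustic
  sum rule still holds. The same construction is elastically isotropic
  ($c_{12} = 0$, $c_{11} = 2c_{44} = \kappa a^2/V$), and because the
  force constants are independent of distance its thermal pressure is
  exactly zero — a null test for the QHA machinery. The default k-grid is
  12×1×1 so the innermost shell sits at $ka/2 = \pi/12$, where the
  sine-vs-linear deviation of the fitted Debye velocity is ~1%.
* `exp6_fcc()` — a four-atom fcc cell bound by one exp-6 interaction
  ($A = 4\times10^5$ kJ mol^-1^, $B = 3$ Å^-1^, $C = 25200$
  kJ mol^-1^ Å^6^, $m = 39.948$ amu), relaxed at construction. The
  parameters put the fixture in the regime of a small-molecule crystal:
  bulk modulus near 10 GPa, lattice modes up to ~125 cm^-1^, cohesive
  energy ~34 kJ mol^-1^ per atom. Its oracle evaluates explicit
  $E(V)$ and $E(V) + F_\mathrm{vib}(V,T)$ scans by direct computation,
  independent of the thermal-pressure path.
* `rigid_diatomic_crystal()` — a rigid heteronuclear diatomic (C–O like,
  bond 1.1 Å, charges ±0.15 e) in two packings that relax to distinct
  mechanically stable minima: "alpha" (parallel-aligned) and "beta"
  (tilted antiparallel). They form a synthetic polymorph pair for the
  full comparison pipeline, with librations, electrostatics and a
  lattice-energy gap of a few tenths of a kJ mol^-1^ — the scale at which
  real polymorphs compete. Both packings are soft and strongly expansive,
  so the pair is compared at a family melting temperature of 120 K, below
  the temperature at which the negative thermal pressure destabilizes the
  softer packing (that failure mode itself is exercised deliberately in
  the error-handling tests).
* `synthetic_pair_ensemble()` — draws pairwise free-energy differences
  with the statistical structure of a large polymorph survey:
  lattice-energy differences (sd 2 kJ mol^-1^, chosen so roughly half of
  all pairs differ by less than 2 kJ mol^-1^), zero-point and harmonic
  vibrational contributions (sd 0.3 and 0.8 kJ mol^-1^), and a
  thermal-expansion contribution normally distributed about zero with
  sd 0.42 kJ mol^-1^. It emulates the book-keeping of a survey, not the
  physics: classification fractions computed from it test the counting,
  never a physical claim.

What passing tests on these crystals shows: the mathematics of the engine
(energies, derivatives, phonons, thermodynamic identities, elastic
algebra, classification logic) is implemented correctly against
independent oracles. What it does not show: that an exp-6/point-charge
model is accurate for any particular real compound — real molecular
crystals have hydrogen bonding, anisotropic repulsion and higher
electrostatic moments that this energy model does not describe, and
0 K lattice-energy errors remain the dominant uncertainty in real
polymorph rankings.

## Known limitations

* Point charges only; no distributed multipoles, no polarization, no
  anisotropic repulsion — absolute lattice energies of real hydrogen
  bonded crystals will be systematically off.
* Rigid molecules only: no intramolecular relaxation, no conformational
  polymorphism.
* The acoustic/optic split is by sorting, which can misassign branches in
  crossing regions; the effect on integrated thermodynamics is small but
  not zero.
* Isotropic thermal pressure: anisotropic cells expand anisotropically
  only through the relaxation at $-P_\mathrm{th}$, not through an
  anisotropic strain-resolved quasi-harmonic functional.
* No negative-thermal-expansion handling: fixtures and defaults assume
  softening with expansion.
```
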