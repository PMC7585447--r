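---
title: "Torsion-space Monte Carlo and folding-landscape analysis with foldmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-space Monte Carlo and folding-landscape analysis with foldmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldmc)
```

## The model

`foldmc` samples peptide conformations with Metropolis Monte Carlo in
torsion space. The degrees of freedom are rotations about rotatable
bonds (backbone φ/ψ and sidechain χ), plus two collective moves; bond
lengths and, except at two junction points of the concerted move, bond
angles are never perturbed. Because the fastest vibrational modes are
frozen out by construction, there is no timestep constraint: each move
is a finite conformational jump whose acceptance is decided by the
Metropolis criterion `min(1, exp(-dE / k_B T))`. All proposal kernels
are symmetric, so the acceptance rule needs no Hastings correction and
the chain converges to the Boltzmann distribution of the potential.

The potential combines AMBER-style intramolecular terms with a two-part
implicit solvent:

* **Bonded**: harmonic bonds `k_b (r - r0)^2`, harmonic angles
  `k_th (theta - th0)^2`, and periodic torsions
  `k (1 + cos(n phi - phi0))`, proper and improper.
* **Nonbonded**: Lennard-Jones and Coulomb sums over all non-excluded
  pairs, with no distance cutoff of any kind. 1-2 and 1-3 pairs are
  excluded; 1-4 pairs are scaled by 0.5 (LJ) and 1/1.2 (Coulomb), the
  convention of the AMBER force-field family whose topologies the
  package reads.
* **Polar solvation**: a generalized Born term,
  `dG = -(k_e/2)(1/eps_p - 1/eps_w) sum_ij q_i q_j / f_GB`, with
  Still's `f_GB = sqrt(r'^2 + B_i B_j exp(-r'^2 / 4 B_i B_j))` and
  self terms `f_GB = B_i`.
* **Nonpolar solvation**: `gamma * SASA` with a Shrake-Rupley surface
  area.

A constant offset `delta = 0.001` Å is added to every interatomic
distance entering the Coulomb, LJ and GB terms. Monte Carlo proposals
occasionally produce near-zero atomic separations; the offset turns the
resulting infinities into large-but-finite energies that are then
rejected normally. The offset applies to interatomic distances only —
GB self terms use the bare Born radius.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `eps_p`, `eps_w` | 1, 80 | — | solute and water dielectrics |
| `gamma` | 5.42 | cal/mol·Å² | nonpolar surface tension |
| `probe` | 1.4 | Å | solvent probe radius |
| `delta` | 0.001 | Å | distance-offset regularization |
| `width_deg` | 20 | deg | SD of dihedral move angles |
| `width_concerted_deg` | = `width_deg` | deg | SD of concerted move angles |
| `concerted_window` | 4 | residues | crankshaft window length |
| `rigid_max_deg` | 5 | deg | rigid-rotation angle bound |
| `move_weights` | 0.45/0.45/0.10 | — | dihedral / concerted / rigid |
| `equil_frac` | 0.10 | — | records discarded as equilibration |
| contact `cutoff` | 4.5 | Å | native-contact heavy-atom distance |
| contact `min_separation` | 3 | residues | minimum sequence separation |
| contact `lambda` | 1.2 | — | formation tolerance on native distance |
| `k_Q` (restraint) | 100 | kcal/mol per unit Q² | Q-wall force constant |

The dihedral move widths of 18.3–20° are the regime where folding
simulations of small helical and β proteins reach accumulated acceptance
ratios near 60%; "width" is read as the standard deviation of the
Gaussian draw, the conventional meaning. Dihedral and concerted moves
are proposed with equal probability; the rigid-rotation share is not
pinned down by that statement, so it defaults to a small 10% and is
fully configurable. Rigid rotations cost one energy evaluation and are
always accepted (the energy is frame invariant), so they act as a cheap
global reorientation rather than a sampling driver. There are no
translation moves: with an implicit solvent there is no box, and the
energy is translation invariant.

Physical constants are `k_e = 332.0636` kcal·Å/mol/e² and
`k_B = 1.9872041e-3` kcal/mol/K.

## The move set in detail

**Dihedral pivot.** One rotatable torsion is chosen uniformly; the atoms
downstream of the pivot bond (the side away from the chain's first atom)
are rotated rigidly about the bond axis by a centered Gaussian angle.
Omega (peptide) bonds and ring bonds are never rotatable, and proline
has no φ — standard practice for torsional samplers.

**Concerted (crankshaft) move.** A contiguous window of 4 residues is
chosen uniformly; all of its atoms except two anchors — the first
residue's backbone N and the last residue's backbone C — rotate rigidly
about the anchor–anchor axis. The anchors lie on the axis, so the
window's endpoints are exactly fixed, several backbone dihedrals at the
junctions change at once, and only the two junction bond angles are
strained, which the angle term then scores. This realization satisfies
the endpoint constraint exactly, is manifestly symmetric, and needs no
loop-closure solver; an analytic loop-closure variant could be swapped
in behind the same interface.

**Rigid rotation.** The whole molecule rotates about a uniformly
distributed axis through its geometric center by an angle uniform on
[0°, 5°].

Every move is a rigid rotation of some atom subset, so no move changes
any bond length — verified to 1e-9 Å in the test suite.

## Numerical choices

* **Born radii.** The pairwise-descreening (HCT) integrals with OBC-II
  tanh rescaling: intrinsic radii offset by 0.009 Å, per-element
  descreening scale factors (H 0.85, C 0.72, N 0.79, O 0.85, S 0.96),
  and rescaling coefficients α = 1.0, β = 0.8, γ = 4.85. This flavor is
  well specified, widely validated, and plays the same physical role as
  proprietary volume-integration methods; all of its knobs live in
  `solvent_params()` so alternatives can be configured. An isolated
  atom's Born radius equals its offset intrinsic radius exactly. The
  test suite compares a buried atom's radius against a numeric
  Coulomb-field volume integration on a grid; that comparison is made
  on an overlapping-sphere cluster (spacing 2.2 Å for carbon radii),
  the bonded-geometry regime the descreening scale factors are fitted
  for — on non-overlapping (merely touching) spheres, scaled pairwise
  descreening systematically undercounts the excluded volume and the
  two methods legitimately diverge.
* **SASA.** Shrake-Rupley quadrature with 960 sphere points per atom
  (configurable), golden-spiral distributed. Atom radii derive from the
  LJ minimum, `r_i = 2^(1/6) sigma_i / 2`, with the 1.4 Å probe; atoms
  with zero LJ size are transparent. The quadrature point set is
  oriented along a molecule-intrinsic frame built covariantly from the
  coordinates, so the computed areas — and hence the total energy — are
  exactly invariant under rigid rotations of the molecule instead of
  carrying ~0.5% orientation noise. Isolated- and two-sphere areas have
  closed forms; the 960-point quadrature reproduces them to better than
  0.5%.
* **Energy bookkeeping.** The sampler recomputes the full energy at
  every step. The GB and SASA terms are global (every atom's Born
  radius and exposed area can change when any atom moves), so
  incremental updates are unsafe without machinery to bound their
  error; correctness by construction was preferred at these system
  sizes. Recorded energies are audited against fresh recomputation in
  the tests.
* **Reproducibility.** A single seeded RNG stream drives every draw.
  The compiled MC loop and the R-level `mc_step()` path consume
  variates in the same order and perform identical floating-point
  arithmetic, and the suite asserts the two produce bit-identical
  chains — a strong self-check that the fast path implements exactly
  the documented algorithm. Temperature series derive per-run seeds as
  `seed + index - 1`.
* **Ties and edge cases.** Ensemble intervals are closed on the left,
  open on the right (an interval ending at 1 includes 1). Empty PMF
  bins are masked (NA), never zero-filled, and masked bins can never be
  minima. Barriers are reported from each flanking minimum separately.
  φ-values with an N/D contrast below 0.1 are flagged undefined rather
  than reported as noise; out-of-range φ are reported, never clipped.
  Rejected MC steps restore the coordinates bitwise.

## The synthetic generator

`generate_fixture_peptide()` builds a polyalanine-like chain with
hydrogens from ideal internal coordinates: near-extended backbone with a
small seeded jitter, bond and angle equilibrium values set to the built
geometry (so harmonic terms are exactly zero at generation), neutral
per-residue charges, per-element LJ and GB radii, and complete
exclusion/1-4 bookkeeping. `generate_toy_dihedral_system()` provides a
four-atom chain whose single torsion has the analytic Boltzmann
distribution `p(phi) ∝ exp(-k(1+cos phi)/k_B T)`;
`generate_single_ion()` and `generate_ion_pair()` give the closed-form
solvation and Coulomb micro-systems.

These fixtures emulate the *structure* of a parameterized protein — the
bond graph, the torsional degrees of freedom, the energy-term coverage —
not its chemistry. They carry plausible but invented parameters, a
single residue type, and an extended geometry with no compact native
state. Tests passing on them demonstrate that the machinery is correct
(energies match oracles, the chain samples the Boltzmann distribution,
moves respect their contracts); they do not demonstrate force-field
accuracy or folding behavior of real sequences, which additionally needs
externally assigned AMBER parameters (e.g. a pdb2gmx-generated topology,
which `read_topology()` accepts in a documented GROMACS-dialect subset).

## Analysis conventions

Q is a hard per-frame count: a native residue pair (heavy-atom minimum
distance < 4.5 Å, |i−j| ≥ 3 in the reference) is formed when its current
minimum heavy-atom distance is below λ = 1.2 times its native value.
The hard count is the default because the Q-restraint wall used to
confine poorly-refolding systems needs a concrete per-frame Q; a smooth
switching-function variant would change only `compute_q`. The reference
structure is whichever frame the user designates (conventionally a
relaxed lowest-energy structure); which one was used is recorded in the
contact set. The absolute Q of the folded minimum depends on all of
these knobs, which is why they are configuration rather than constants.

φ-values are Boltzmann-weighted within each ensemble
(`w ∝ exp(-E/k_B T)`, normalized per ensemble) and default to the
normalized form `(⟨q⟩_TS − ⟨q⟩_D) / (⟨q⟩_N − ⟨q⟩_D)`; the unnormalized
`⟨q⟩_TS` is returned alongside since both conventions appear in the
φ-value literature. The transition-state window defaults to
Q ∈ [0.55, 0.65], bracketing the barrier-top region near Q ≈ 0.6 where
two-state folders show their light band in per-residue stability maps.

Temperature calibration (`calibrate_temperature()`) is a user-supplied
constant shift applied to reported temperatures only — implicit-solvent
models lack the solvation entropy's temperature dependence and
systematically overestimate folding temperatures, and aligning the heat
capacity peak with an experimental melting temperature is the natural
source of such a shift. The package deliberately does not guess the
shift itself; raw simulation temperatures are always preserved.

## Problem sizes

The test suite and the acceptance script run entirely on generated
systems at sizes chosen to keep every check sharp: 22–92-atom peptides
for the O(N²) oracle comparisons, a 13-atom cluster for the Born-radius
grid oracle, 10⁶ MC steps for the Boltzmann goodness-of-fit (a
one-dihedral system, seconds of compute), and 2×10⁴ full-energy steps
for the acceptance-ratio report on an 8-residue peptide. Landscape
reproduction for real proteins is a driver-level exercise on top of the
same functions: the published protocols use 2×10⁸ steps per trajectory
at 5–10 temperatures, which is a cluster-scale budget by design, not a
package limitation in kind — only in time.

## Known limitations

* The implicit solvent has no temperature dependence, which (as with
  all GBSA-type models) overstabilizes folded states and solvent-exposed
  salt bridges and shifts folding temperatures upward; the calibration
  shift is a reporting-level correction, not a fix.
* Pairwise-descreening Born radii are approximate for non-bonded
  packing geometries (see above); a volume-based GB or a
  Poisson-Boltzmann reference would be the upgrade path.
* The concerted move strains the two junction angles rather than
  solving loop closure exactly; at the default widths the angle term
  keeps this strain small, but very wide concerted moves are accepted
  rarely.
* No kinetics: Monte Carlo step counts are not physical time, and the
  package computes only thermodynamic observables.
* Hydrogens must be present in the input structure; the package assigns
  neither protonation states nor missing atoms.
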