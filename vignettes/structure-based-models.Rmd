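---
title: "Structure-based models: topology generation, dynamics and folding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based models: topology generation, dynamics and folding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmr)
```

## The model

A structure-based ("Go-type") model encodes a known native structure as the
global minimum of the potential energy function. For the single-bead-per-residue
(C$_\alpha$) protein model the Hamiltonian is

$$
H(\mathbf{x},\mathbf{x}^0) =
\sum_{ij\in\mathrm{bonds}}\frac{\epsilon_b}{2}\left(r_{ij}-r^0_{ij}\right)^2
+\sum_{ijk\in\mathrm{angles}}\frac{\epsilon_\theta}{2}\left(\theta_{ijk}-\theta^0_{ijk}\right)^2
+\sum_{ijkl\in\mathrm{dihedrals}}\epsilon_D\,F_D\!\left(\varphi_{ijkl}-\varphi^0_{ijkl}\right)
$$
$$
+\sum_{ij\in\mathrm{contacts}}\epsilon_C\left[5\left(\frac{r^0_{ij}}{r_{ij}}\right)^{12}
-6\left(\frac{r^0_{ij}}{r_{ij}}\right)^{10}\right]
+\sum_{ij\notin\mathrm{contacts}}\epsilon_{NC}\left(\frac{\sigma_{NC}}{r_{ij}}\right)^{12},
$$

with the dihedral form

$$
F_D(\delta\varphi)=\left[1-\cos\delta\varphi\right]+\tfrac12\left[1-\cos 3\delta\varphi\right].
$$

Every superscript-0 quantity is measured on the input structure, so the native
configuration minimizes each structure-derived term exactly: bond, angle and
dihedral terms vanish there and each native contact contributes $-\epsilon_C$.
The backbone is maintained by the stiff bonds and angles, secondary and
tertiary structure by the dihedral and contact terms, and everything else
interacts only through the $r^{-12}$ excluded volume.

## Templates: a declarative forcefield grammar

The model is not hard-coded. A *template set* (four XML documents per
directory: residue definitions, function declarations and system settings,
bonded rules, nonbonded rules; schema in `inst/templates/SCHEMA.md`) declares

* the atoms and covalent bonds of every residue, each atom carrying three
  type tokens (bonded, nonbonded, pair type) plus charge and mass (defaults
  0 and 1 in reduced units);
* the functional forms available (harmonic bond/angle, the $F_D$ dihedral,
  12-10 / Gaussian / harmonic contacts, $r^{-12}$ excluded volume);
* typed interaction rules whose parameter slots are either numbers or the
  `?` placeholder, which requests the value measured from the native
  structure (a bond rule `bond_harmonic(?,20000)` gives every matched bond
  the native length and $\epsilon_b = 20000\,\epsilon\,\mathrm{nm}^{-2}$).

Rule matching is whole-token, orientation-symmetric, and most-specific-wins
(number of literal, non-`*` tokens). An equal-specificity tie between two
distinct rules is an *error*, not a preference: template ambiguity is a bug
in the template and the user must supply an exact rule. A full-wildcard rule
makes matching total, which the bundled sets exploit.

Bundled sets: `sbm_ca` (one C$_\alpha$ bead per residue, 12-10 contacts),
`sbm_ca_gaussian` (Gaussian contact wells), `sbm_aa` (all heavy atoms,
proper dihedrals only), `enm` (all-atom elastic network: no covalent terms,
harmonic springs on all atom pairs within the cutoff, uniform stiffness).

Choices the sources leave open, decided here:

* **Gaussian contact form.** The literature uses several variants; the
  shipped form is the plain well
  $V(r) = -\epsilon_C \exp\!\left(-(r-r^0)^2/2w^2\right)$ with width
  $w = 0.05$ nm. This is an implementation choice, configurable per rule.
* **ENM spring stiffness** is not fixed by the sources ("system
  independent"); the bundled value is $1000\,\epsilon\,\mathrm{nm}^{-2}$.
* **All-atom energetic normalization.** The convention that ties total
  stabilizing energy to system size and fixes the contact/dihedral ratio is
  provided as `normalize_energies()` (defaults: ratio 2, total = atom
  count). These constants are provisional; anyone needing bit-compatibility
  with a specific published all-atom parameterization must check them.
* **C$_\alpha$ constants.** Only $\epsilon_b = 20000$ is fixed by the
  sources; $\epsilon_\theta = 40\,\epsilon/\mathrm{rad}^2$,
  $\epsilon_D = \epsilon_C = \epsilon_{NC} = 1$, $\sigma_{NC} = 0.4$ nm
  follow the standard C$_\alpha$ model family and are all template-editable.

## From structure to topology

`read_pdb()` parses fixed-column PDB records, converting to nm once at parse
time (all internal lengths are nm; this avoids mixed-unit bugs). Chain
identity: a TER record, a chain-id change, or a residue-numbering gap whose
flanking residues are farther apart than a bondable 0.3 nm starts a new
physical chain. Alternate locations other than blank/'A' are dropped with a
warning; models beyond the first are ignored with a warning; insertion codes
are kept and treated as distinct residues. Residue numbering is used only
for identity — covalent connectivity always follows template declarations
and chain breaks.

`adjust_names()` reconciles common PDB naming variants against the template
vocabulary through an editable alias table (terminal oxygens, histidine
protonation names); undeclared hydrogens are dropped silently, other
undeclared atoms with a warning (or kept, for single-template
coarse-graining pipelines, where they still feed the atomic contact map).

`build_bond_graph()` instantiates per-residue template bonds, joins
consecutive residues within a chain through the declared connect atoms, and
appends user-supplied extra bonds (the escape hatch for irregular chains).
Angles and dihedrals are then *derived from the graph*: every simple path
i–j–k (once, with i < k) and every simple path i–j–k–l around each central
bond (canonical orientation i < l; three-cycles skipped). `assemble_topology()`
parameterizes every term by rule matching plus placeholder resolution and
computes the exclusion set: all pairs within `exclusion_depth` bonds
(default 3, standard `nrexcl` semantics) plus all contact pairs. A contact
that coincides with a covalent bond is dropped (with a warning when the
contact list was user-supplied).

Native contact maps come from `cutoff_contact_map()` (distance cutoff,
default 0.6 nm — the 6 Å heavy-atom convention — with a residue-separation
floor; inter-chain pairs always eligible), optionally screened by
`occlusion_filter()`, which removes a pair when any third atom lies within
`screening_radius` (default 0.1 nm) of the segment joining it. The
occlusion filter is a deliberately simple line-of-sight criterion — a
stand-in for shadow-style screening, not a reproduction of that algorithm's
atom-radius geometry. Coarse-graining (`coarse_grain()`) keeps the single
template-designated atom per residue; `map_contacts_to_cg()` projects the
atomic map onto beads (a residue pair is a bead contact iff at least one
atomic contact joins the residues and the separation is at least 4), with
the native distance re-measured between beads.

## Topology files

`write_top()`/`read_top()` speak a GROMACS-dialect `.top` with fixed section
order and 1-based indices. Conventions are written into every file header;
the two that prevent classic bugs:

* GROMACS stores harmonic stiffness $k$ with $V = (k/2)\delta^2$ and the
  Hamiltonian writes $\epsilon_b/2\,\delta^2$, so $k = \epsilon_b$ *exactly*
  — no factor of two;
* each dihedral becomes two periodic lines
  $V = k[1+\cos(n\varphi - \mathrm{phase})]$ with
  $\mathrm{phase}_n = n\varphi^0 + 180^\circ$, multiplicity 1 at full and 3
  at half strength, which reproduces $F_D$ exactly; the reader re-merges the
  pair.

Angles are degrees in the file (radians internally), 12-10 contacts are
emitted as explicit coefficients $C_{12} = 5\epsilon_C (r^0)^{12}$,
$C_{10} = 6\epsilon_C (r^0)^{10}$ (minimum at $r^0$, depth $-\epsilon_C$),
and floats use scientific notation with 9 significant digits so regenerated
files are byte-identical. Stock GROMACS interprets `[pairs]` as 6-12; these
files target the bundled simulator (which reads the dialect natively) or an
SBM-aware build.

## The simulator

Reduced units throughout: $\epsilon = 1$, $k_B = 1$, mass 1, lengths nm.
Temperatures map to simulation-package (mdp) values through
$T_{\mathrm{mdp}} = T/0.00831451$ (the reduced energy unit taken as 1
kJ/mol); 1.17 maps to 140.7, 0.97 to 116.7.

The integrator is Langevin dynamics with BAOAB splitting, which reduces to
velocity Verlet at $\gamma = 0$ (used by the energy-conservation tests) and
has very accurate configurational sampling at finite friction. Defaults
$dt = 5\times10^{-4}$, $\gamma = 1$: with the stiffest default term
($\epsilon_b = 2\times10^4$, bond frequency $\omega \approx 200$ for the
dimer's reduced mass) this gives $\omega\,dt \approx 0.1$, comfortably
stable. Randomness comes from one counter-based PCG32 stream seeded once,
with Gaussian draws in fixed atom order, so trajectories are bit-identical
for a given seed.

Excluded volume uses a Verlet neighbor list (skin 0.25 nm, rebuilt when any
atom has moved half a skin) with the potential shifted to zero at the
cutoff. The default cutoff 0.8 nm truncates $(\sigma_{NC}/r)^{12}$ at
$\sim 2\times10^{-4}\,\epsilon$ for $\sigma_{NC} = 0.4$ — negligible
against the contact scale. `compute_energy()`/`compute_forces()` evaluate
untruncated sums over all non-excluded pairs; the slow pure-R reference
implementation used to validate them lives with the tests, not the package.
Degenerate geometry is regularized rather than fatal inside the integrator
(near-collinear angle/dihedral configurations contribute no force for that
term at that step), while `measure_geometry()` — which defines *native*
parameters — treats degeneracy as an error. A coordinate exceeding $10^6$
aborts the run with a diagnostic.

## Analysis

* `compute_q()`: fraction of native contacts within `ratio` times their
  native distance (default 1.5; 1.2 is the stricter convention). Invariant
  under rigid motions by construction.
* `free_energy_profile()`: $F(Q) = -\ln P(Q)$ in $k_BT$, histogrammed over
  [0, 1] (default 40 bins — roughly one bin per few contacts for a
  64-residue-scale map), minimum shifted to zero, defined only on visited
  bins.
* `specific_heat()`: $C_v(T) = (\langle E^2\rangle - \langle E\rangle^2)/T^2$
  per temperature, optional equal-area normalization, peak refined by
  quadratic interpolation.
* `estimate_tf_from_profiles()`: the profile with the highest barrier
  between its two deepest minima fixes the basin-splitting $Q$ (ties toward
  lower $Q$); $T_F$ is where the folded fraction crosses 1/2, by linear
  interpolation across temperatures. Multi-temperature histogram reweighting
  is deliberately out of scope, so $T_F$ rests on independent runs plus the
  $C_v$ peak cross-check.
* `contact_formation_map()`: per-contact formation frequencies over the
  frames in a Q window (e.g. the unfolding side of the barrier at
  $Q = 0.30$), with `contact_map_difference()` for model comparisons.
* `compute_com_pca()`: mass-weighted centre of mass per domain per frame,
  mean-centred, covariance eigendecomposition; eigenvalues in nm$^2$ sum to
  the total COM variance. This is the tool for global-mode analysis of
  large assemblies.

## The synthetic 64-residue folder

Desk-scale folding experiments need a small two-state protein.
`make_ci2_synthetic()` builds one deterministically: 64 residues, an
$\alpha$-helix packed against a four-stranded antiparallel sheet — the size
and architecture of the chymotrypsin-inhibitor-2 class — represented by
C$_\alpha$ atoms plus one side-chain centroid (CB) 0.25 nm away (none for
glycine). Strand spacing 0.48 nm, ideal-helix trace scaled to exact 0.38 nm
C$_\alpha$ steps, loops as uniform-spacing circular arcs bulging away from
the body, termini packed along the sheet. The geometry was accepted against
two structural criteria, fixed before any folding run: no
sequence-distant atom pair below 0.30 nm, and a coarse-grained contact
density (~2.1 contacts/residue at the centroid criterion below) typical of
compact single-domain proteins.

For this reduced representation the atomic 0.6 nm cutoff undercounts
contacts (two pseudo-atoms cannot interdigitate the way eight heavy atoms
do), so the folding testbed (`ci2_synthetic_model()`) uses the standard
side-chain-centroid contact convention, 0.8 nm between centroids, before
projecting onto beads with sequence separation $\ge 4$. That yields 134
native contacts over 64 beads. One known consequence of the representation:
helix $i,i{+}4$ pairs sit just outside any centroid criterion, so helical
structure is stabilized almost entirely by the dihedral terms — which is
how the C$_\alpha$ model family works anyway.

What passing the folding tests does and does not show: the synthetic fold
reproduces the *class* behaviour (two-state folding, a bimodal $F(Q)$ with
a barrier near $Q \approx 0.4$–0.6, folding temperature near 1.1–1.2
reduced units, agreeing $C_v$-peak and population estimates). It is not the
crystallographic protein, so quantitative transition-state composition or
per-contact formation patterns of the real protein are outside what these
tests can certify. Real-structure workflows (full heavy-atom maps, the
all-atom template, experimental structures) use exactly the same code paths
and are exercised structurally by the test suite; all-atom folding
thermodynamics needs sampling far beyond a desk-scale run and is supported
as an extended-run regime rather than a routine test.

## Problem sizes used by the shipped experiments

The folding experiments in the test suite and the acceptance script scan
five temperatures (0.95–1.35) with $4$–$6\times10^6$ steps each at
$dt = 5\times10^{-4}$ (2 000–3 000 reduced time units per temperature,
several folding/unfolding events near the transition), discarding the first
20% of each run. Equipartition and distributional checks on the dimer use
$2$–$3\times10^6$ steps. These sizes were chosen as the smallest that give
stable estimates of $T_F$ (both estimators within ~0.05) across seeds.

## Known limitations

* The occlusion filter is a line-of-sight approximation, not a full
  atom-radius shadowing construction.
* `sbm_aa` ships proper dihedrals only (no improper/planarity terms) and
  the published heterogeneous-radius hydrogen variant is not included
  (its radii table is not available here).
* Electrostatics (charged model variants) are not implemented; charges are
  carried through the data model and file formats only.
* Multi-basin merging, replica exchange, WHAM, constraints and kinetics
  analysis are out of scope.
* The `.top` dialect is self-consistent and round-trip stable but not
  claimed byte-compatible with any external generator's output.
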