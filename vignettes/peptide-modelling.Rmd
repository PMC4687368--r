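---
title: "Modelling modified peptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling modified peptides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pepbuildr` predicts all-atom models of short peptides (7–25 residues)
from sequence plus secondary-structure and β-turn annotations, handles
the common covalent modifications of therapeutic peptides, refines the
models with a small molecular-mechanics engine, and evaluates them
against experimental multi-model ensembles.  This vignette explains the
model, the parameters that matter, the numerical choices, and what the
bundled synthetic fixtures do and do not demonstrate.

## From annotations to restraints

The central assumption is that a short peptide's backbone is well
approximated by canonical secondary-structure geometry: helix residues
get (φ, ψ) = (−60, −40), strand residues (−120, 120), and coil residues
(180, 180) — the extended conformation, so that unannotated peptides
start from a maximally open chain rather than a guessed fold.  β-turn
annotations override positions *i*+1 and *i*+2 of each four-residue
turn with that turn type's canonical angles.

Design choices that were genuinely open:

* **Turn table.** The turn types are identified by name (I, I′, II,
  II′, IV, VIII); the bundled (φ, ψ) values are the classic
  crystallographic consensus angles for those types
  (`inst/extdata/turn_types.tsv`).  The table is a data file and can be
  replaced wholesale by the user.
* **Restraint extent.** Only *i*+1 and *i*+2 carry turn angles;
  residues *i* and *i*+3 keep their secondary-structure assignment.
  The alternative (restraining all four positions) over-commits the
  flanks when turns border regular structure.
* **Priority.** Turn angles override helix/strand assignments at the
  same position, and overlapping turns resolve last-annotation-wins.
  Turns are the more specific annotation, and a deterministic rule
  keeps rebuilds reproducible.
* **ω.** All peptide bonds are built trans (ω = 180°); cis-proline
  isomers are out of scope.

External predictors are deliberately not bundled: the library takes
annotation strings (3-state, or DSSP 8-state which is reduced by
`reduce_dssp`: G,H→H; B,E→E; rest→C).  When no annotation is supplied,
`pep_predict` falls back to all-coil and says so prominently.  For
sequences containing non-natural residues, `mask_nonnatural` produces
the string to hand to sequence-based predictors: non-natural codes
become `X`, while D-residues and PTM-carrying residues keep their
parent letter (their local sequence context is still informative).

## Building coordinates

Chains are grown in internal coordinates (NeRF): each atom is placed
from a bond length, a bond angle and a torsion relative to three placed
atoms, with standard backbone geometry (N–Cα 1.458 Å, Cα–C 1.525 Å,
C–N 1.329 Å).  The builder reproduces requested φ/ψ to floating-point
accuracy (the test suite checks 100 random restraint vectors at
1e-3°), and the construction is exactly equivariant under rigid motion
of the seed frame.

Side chains come from residue **templates** — one plain-text file per
residue type carrying atoms (element, partial charge, Lennard-Jones
parameters), a z-matrix for every atom beyond the backbone frame,
ring-closure bonds, and χ definitions.  χ slots are filled from a
coarse backbone-dependent rotamer library (three bins at the helix,
strand and extended backbone angles; nearest-bin lookup; χ1 preferences
over gauche−/trans/gauche+ with bin-dependent weights).  Ties in
rotamer probability break to the lowest row index, and residues without
a library entry fall back to all-trans template χ (logged).  The
bundled rotamer weights and the non-natural templates (ornithine-like,
Aib-like, phosphoserine-like, hydroxyproline-like) are physically
plausible placeholder parameterizations written for this package — they
emulate the *shape* of published force-field libraries without copying
any of their values, and users can register their own templates at run
time.

**Chirality.**  A D-residue is built (or an L-residue converted by
`set_chirality`) by negating every side-chain/αH torsion relative to
the local N–Cα–C frame — an exact geometric mirror that preserves all
bond lengths and angles, flips the Cα improper's sign, and is an
involution.  Rotamers for D-residues are looked up at the mirrored
backbone angles (−φ, −ψ) and negated, so an all-D peptide built with
sign-flipped restraints is the exact reflection of the all-L build
(verified to < 1e-3 Å RMSD in the tests).

**Protonation.**  Ionizable side chains are built in their pH-7
canonical states (Lys/Arg +1, Asp/Glu −1, His neutral NE2-H tautomer,
phosphoserine −2); free termini are zwitterionic.  No
hydrogen-bond-optimized protonation is attempted.

## Covalent modifications

Caps replace the zwitterionic termini (acetyl at N; amide or
N-methylamide at C) as pseudo-residues 0 and *n*+1.  Cyclization is a
*topology patch*: the SG–SG (equilibrium 2.05 Å) or N–C (1.329 Å) bond
term, plus standard angle and ω-style torsion terms across it, are
added and the displaced atoms (thiol hydrogens; OXT and two ammonium
hydrogens) deleted — but the geometry is **not** closed at patch time.
Closure is delegated to minimization, mirroring the bond-then-relax
flow of structure-modification pipelines; the tests verify both bonds
land within 0.1 Å of their equilibria after minimization from a fully
extended build.

## The refinement engine

The energy is a standard fixed-charge molecular-mechanics form:
harmonic bonds and angles, periodic dihedrals, harmonic impropers
(sp² planarity and Cα chirality), 12-6 Lennard-Jones and Coulomb.
Units are kcal/mol, Å, fs, amu throughout.

Parameter policy: bond, angle and improper *equilibria* are taken from
the as-built ideal geometry (the templates define that geometry), so a
freshly built model starts with zero bonded strain; patch terms carry
explicit standard equilibria because the patched geometry is unclosed.
Force constants are generic plausible values (heavy-heavy bonds
300 kcal/mol/Å², X–H 340, S–S 166; angles 50/35 kcal/mol/rad²;
sp³ torsion barriers 1.4 kcal/mol 3-fold, amide/aromatic 10 kcal/mol
2-fold).  1-2/1-3 pairs are excluded; 1-4 LJ is halved and 1-4 Coulomb
scaled by 1/1.2.

* **Cutoff.**  Nonbonded interactions default to a 10 Å cutoff (the
  legacy 8 Å behaviour is a flag away) with a cubic switching function
  over the last 2 Å.  The switch matters: bare truncation injects
  force discontinuities that destroy energy conservation in vacuum MD.
* **Minimization.**  Steepest descent with Armijo backtracking (default
  1000 steps) then Polak-Ribière conjugate gradient (1000 steps,
  restart on non-descent).  The SD energy trace is non-increasing by
  construction; convergence stops early below a 1e-6 kcal/mol/Å
  gradient infinity-norm.
* **Dynamics.**  Velocity Verlet at 1 fs with seeded Maxwell–Boltzmann
  initial velocities, a linear 0→300 K target ramp over the heating
  phase (default 50 ps; far shorter in tests), and Berendsen
  weak-coupling (τ = 0.1 ps) during production.  The scaling factor λ
  is clamped to [√0.5, √2] so near-zero instantaneous temperatures
  cannot blow up the first steps.  No barostat: vacuum runs have no
  pressure coupling, and no periodic boundary conditions are used.
  With the thermostat disabled the integrator is plain NVE, which is
  how the conservation check runs (< 0.1 % drift at 0.2 fs).
* **Delegation.**  `delegate_water` / `delegate_hydrophobic`
  environments return a run description (structure + topology +
  protocol) for an external solvated-MD engine instead of running;
  re-implementing explicit-solvent electrostatics is out of scope.

The analytic gradient is verified against central finite differences at
1e-5 relative error, and the energy is invariant under rigid motion —
both are part of the test suite, not one-off checks.

## Evaluation

Hydrogens are stripped from both sides before any metric.  For
multi-model references the declared representative conformer is the
reference, else model 1.  Kabsch SVD superposition (determinant
corrected to +1) yields RMSD over all heavy atoms, Cα only (CA-RMSD),
or the backbone set {N, CA, C, O} (B-RMSD) — the carbonyl O is included
in "backbone" here, switchable by selection.  Atom correspondence is by
(residue position, atom name); no sequence alignment is attempted,
since compared structures share a sequence.

The **rigid core** is computed by superposing every model onto model 1
over all Cα (a single pass; iterative-mean refinement is available
behind a flag), taking each residue's Cα RMS fluctuation about its mean
position, and keeping residues below 1.5 Å.  Dataset filters reproduce
the benchmark-construction rules: length within [7, 25], no disulfide,
first occurrence of each sequence.

## What the synthetic fixtures show — and what they do not

The fixture generators build ideal-geometry peptides through the real
pipeline and perturb them with seeded i.i.d. Gaussian coordinate noise
(per-residue alternating-sign displacements engineer non-core
residues).  This exercises every code path deterministically and gives
analytically predictable statistics (CA RMSF ≈ √3·σ), which is exactly
what the property tests need.  It is **not** a physical model of NMR
ensembles: real conformational variability is correlated along the
chain, anisotropic and restraint-driven, so passing these tests
demonstrates correctness of the machinery, not predictive accuracy on
real peptides.  Reproducing published benchmark RMSDs would require the
experimental PDB entries, external secondary-structure/turn predictors
and production force fields, all outside this package.

Problem sizes were chosen to keep the default test run comfortable on a
single CPU: 7–15-residue fixtures, minimization runs of a few hundred
steps, and MD segments of 0.1–1.6 ps (at 0.2–1 fs) — long enough for
the conservation and thermostat statistics being asserted, and the
protocol object scales to the full 2000-step / 50 ps + 100 ps defaults
unchanged.

## Known limitations

* The force field is a generic teaching-grade parameterization;
  energies are useful for relaxation and sanity checks, not for free
  energies or binding.
* Proline and hydroxyproline rings are closed by a topology bond (and
  relaxed by minimization) rather than built ring-closed in internal
  coordinates.
* The builder assumes trans peptide bonds and pH-7 protonation.
* In-house MD is vacuum-only; solvated environments are delegated.
* The rotamer library is deliberately coarse (three backbone bins);
  side-chain packing quality is limited accordingly.
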