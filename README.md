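# pepbuildr

Tertiary-structure modelling of short peptides (7–25 residues), including
the residue modifications that matter for therapeutic peptides: D-amino
acids, N/C-terminal caps, head-to-tail and disulfide cyclization, and
non-natural or post-translationally modified side chains supplied as
plain-text residue templates.

## The problem and the method

Short bioactive peptides rarely have enough sequence context for
template-based protein structure prediction, but their backbone geometry
is strongly constrained by secondary structure and β-turns.  `pepbuildr`
turns per-residue annotations into backbone torsion restraints

| state | φ (deg) | ψ (deg) |
|-------|---------|---------|
| helix (H)  | −60  | −40 |
| strand (E) | −120 | 120 |
| coil (C)   | 180  | 180 (extended) |

with β-turn types (I, I′, II, II′, IV, VIII) overriding positions *i*+1
and *i*+2 of an annotated turn from a bundled canonical (φ, ψ) table.
An all-atom model is then constructed in internal coordinates (NeRF
chain extension: each atom placed from a bond length, bond angle and
torsion), side chains are set from a backbone-dependent rotamer library,
and modifications are applied:

* **D-residues** — the side-chain/αH subtree is built mirrored through
  the local N–Cα–C plane (torsion signs flipped);
* **caps** — acetyl (N-terminus), amide / N-methylamide (C-terminus);
* **cyclization** — disulfide SG–SG (2.05 Å) and head-to-tail N–C
  (1.329 Å) bonds are patched into the topology and closed by
  minimization;
* **non-natural / PTM residues** — any residue described by a template
  file (atoms, charges, Lennard-Jones parameters, z-matrix, χ
  definitions); ornithine-, Aib-, phosphoserine- and
  hydroxyproline-like templates ship with the package and the registry
  is user-extensible.

Models are refined with a lightweight molecular-mechanics engine
(harmonic bonds/angles, periodic dihedrals, impropers, 12-6 LJ +
Coulomb with a 10 Å switched cutoff): steepest-descent then
conjugate-gradient minimization, optionally followed by short vacuum MD
(velocity Verlet, 1 fs, Maxwell–Boltzmann start, linear heating ramp,
Berendsen weak-coupling thermostat at 300 K).  Solvated environments
are exposed as a delegation interface for an external engine, not
simulated in-house.

Evaluation mirrors standard practice for flexible NMR peptides:
hydrogens are stripped, the declared representative model (else model 1)
of a multi-model ensemble is the reference, Kabsch least-squares
superposition yields RMSD / CA-RMSD / B-RMSD ({N, CA, C, O}), and an
ensemble **rigid core** — residues with < 1.5 Å Cα RMS fluctuation
across models — restricts the comparison to the ordered region.

## Worked example

```r
library(pepbuildr)

res <- pep_predict("
sequence: CAKLAEAC
n_cap: acetyl
disulfides: [[1, 8]]
residues:
  - {position: 4, chirality: D}
", ss = "CCHHHHCC",
   protocol = md_protocol(minimize_sd_steps = 100,
                          minimize_cg_steps = 200, seed = 5),
   output_pdb = "model.pdb")

res$energy
#> <energy_report> total -101.2192 kcal/mol
#>   bond 7.6397  angle 19.6671  dihedral 54.4084
#>   improper 7.2288  lj -0.9843  coulomb -189.1789

measure_distance(atom_xyz(res$structure, 1, "SG"),
                 atom_xyz(res$structure, 8, "SG"))
#> [1] 2.066934
```

The printed energy is the component-wise molecular-mechanics energy of
the minimized model (kcal/mol); the SG–SG distance shows the disulfide
patch closed to near its 2.05 Å equilibrium.  Comparing a prediction
with a multi-model reference:

```r
rep <- pep_evaluate("model.pdb", "experimental.pdb")
# columns: rmsd, ca_rmsd, b_rmsd, reference_model, core_ca_rmsd, ...
```

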