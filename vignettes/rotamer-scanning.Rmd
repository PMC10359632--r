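---
title: "Structure-specific rotamer scanning: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-specific rotamer scanning: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiscan)
library(dplyr)
```

## The problem

Classical rotamer libraries are statistical summaries: the frequent
side-chain χ angles of a curated subset of the PDB, optionally binned by
backbone φ/ψ. They are fast to apply but average away the influence of a
residue's actual surroundings, and they cannot offer conformations that
the curated subset never contained — rare rotamers at binding sites,
strained conformations forced by neighbouring atoms, or side chains of
residue types too rare for statistics.

`chiscan` instead builds the library *from* the target structure. For
every chi-bearing residue it scans the full χ-angle grid against the
residue's own rigid backbone environment, scores each conformation with
a weighted pairwise physics model, and keeps every conformation whose
energy lies within a window of the per-residue minimum. The result is a
per-residue list of sterically and energetically admissible rotamers,
with an energy breakdown attached to each.

## The model

### Kinematics

Side-chain geometry is treated as rigid except for rotations about the
χ bonds (at most four; bond-angle bending and bond-length changes are
out of scope). Each atom's position is a product of homogeneous 4×4
transforms: frame changes `T` that place the rotating bond on the local
Z axis, interleaved with rotations `R(χ_i)` about that axis,

p′ = T⁻¹₍₁₎ R(Δχ₁) (T₁T₂⁻¹) R(Δχ₂) ⋯ R(Δχ_g) (T_g p).

All bracketed products are independent of χ and are pre-multiplied once
per residue when the chain is built (`build_transform_chain()`), so a
grid point costs `g` small matrix products. Rotations are applied as
*offsets from the measured input conformation*, which makes evaluating
the chain at the measured χ vector reproduce the input coordinates to
machine precision — a property the test suite checks against an
independent sequential axis-angle (Rodrigues) implementation for all 17
supported residue types.

Proline is excluded: its χ angles are coupled through the
pyrrolidine ring, so a meaningful scan would need the bond-angle and
bond-length degrees of freedom this model deliberately omits. Glycine
and alanine have no χ angle to scan.

### Energy

Each conformation is scored as

E = Σ_pairs Q(r) · (w₁·E_LJ + w₂·E_C + w₃·E_H) + Σ_d w₄·E_T(χ_d)

with Lennard-Jones `ε[(r_min/r)¹² − 2(r_min/r)⁶]`, Coulomb
`k_e·q_i·q_j/r` (constant dielectric 1; `w₂` absorbs any overall
scale), a 12-10 hydrogen-bond well on donor–acceptor heavy-atom pairs,
and a cosine switching factor `Q(r)` that takes every nonbonded term
continuously (and C¹-continuously) from 1 at 2.5 Å to 0 at 5 Å.
Torsion terms `Σ(V/2)(1 + cos(nχ − γ))` are applied per rotating bond;
for incremental accounting they can be distributed over the 1-4 atom
pairs spanning the bond, and the distributed parts sum to the closed
form exactly.

Pairs at bonded distance 1-2 and 1-3 are excluded; 1-4 pairs enter at
full weight (the torsion terms are meant to be calibrated jointly with
this convention). Interactions are computed only between the scanned
side chain and main-chain atoms (N, CA, C, O, OXT plus CB) of
surrounding residues — not between two flexible side chains — plus the
residue's own backbone, exactly the environment a backbone-dependent
library conditions on. Non-polymer (HETATM) atoms within reach are kept
as rigid nonbonded environment; they are never covalently bonded to the
polymer by the geometric bond detector.

Energies are nominally kcal/mol, but every decision the scanner takes
depends on energy *differences* and the weights absorb units, so only
the relative scale matters.

### Environment selection and cubing

A scanned atom can never lie farther from CA than the all-trans
extension of arginine (≈7.3 Å at ideal geometry, computed at run time
from the fixture builder, not hard-coded), so environment atoms are
collected within `reach = extension + 2·max(vdW) + cutoff_end` of the
target CA. Both this query and covalent-bond detection use a cell-list
("cubing") grid; the bond grid uses an edge of twice the largest
covalent radius. Grid queries search as many neighbouring cells as the
query radius requires, so their results are identical to an
all-against-all scan for any edge — a property tested on random point
sets.

### Bond detection

The explicit per-residue bond list in the parameter file is
authoritative for residues it covers; everything else — peptide bonds,
disulfides, unknown residue types — falls back to the geometric
criterion `0.5 Å < d ≤ r_cov(A) + r_cov(B) + 0.4 Å` using Pyykkö
covalent radii. The 0.4 Å slack and the 0.5 Å duplicate-atom floor are
fixed, configurable choices; both comparisons are inclusive.

### Dead-end elimination

The scan is a depth-first traversal of the χ grid, placing the atoms
moved by χ_g at depth `g` and accumulating the partial energy. A branch
is pruned when

partial + bound(g) > best_total_so_far + window,

where `bound(g)` is an *admissible* lower bound on everything still
uncomputed: for every future atom pair the analytic minimum of its
weighted pair potential over all distances ≥ 0.5 Å (LJ ≥ −ε, Coulomb ≥
−k_e|q_iq_j|/0.5 for opposite charges, H-bond ≥ −ε_hb, combined by
interval arithmetic so arbitrary weight signs stay admissible), plus
the minimum of each unset torsion term. Because the bound never
overestimates, a pruned branch can never contain a rotamer the window
would accept: the DEE result equals exhaustive enumeration exactly,
which the acceptance suite verifies residue by residue.

The measured input conformation is always evaluated as an extra,
off-grid candidate. This seeds the incumbent for pruning and guarantees
that a sterically valid observed conformation survives its own scan —
the basis of the self-evaluation-zero property.

### Symmetry

For ASP χ₂, GLU χ₃ and PHE/TYR χ₂ the 180° flip exchanges chemically
equivalent atoms (OD1/OD2, OE1/OE2, ring CD/CE pairs), so scanning
[−90°, 90°) suffices; `scan_spec(symmetry_reduced = TRUE)` enables
this, and the accepted set unfolds onto the full-range scan with
identical energies because the shipped parameters give the exchanged
atoms identical charges, LJ classes and H-bond roles, and the torsion
terms about those bonds use even periodicity. ASN χ₂ and GLN χ₃ are
*always* scanned in full — the flip there swaps an amide O against an
N, which only crystallographic benchmarking treats as equivalent — and
their folding is applied at evaluation time only, behind the
`benchmarking` flag.

## Evaluation metrics

`bc_rmsd()` returns the minimum RMSD between the observed side-chain
heavy atoms and any candidate rotamer, minimised additionally over the
applicable atom-name symmetry permutations. **No superposition is
performed**: candidates are built on the observed backbone, so both
conformations share the structure frame; this matches the protein
modeller's question ("can the library place atoms where the density
says they are") rather than the shape-comparison question a fitted RMSD
answers. `bc_da()` reports the signed circular χ differences (observed
minus selected candidate, in (−180°, 180°]) of the bcRMSD-selected
rotamer, folded into (−90°, 90°] for symmetric χ.

Residues with bcRMSD ≥ 0.1 Å are flagged as outliers — roughly the
coordinate-error scale of good crystal structures — and, among those,
residues with any |bcDA| > 10° are angle outliers. Both thresholds are
boundary-inclusive on the RMSD side and strict on the angle side, and
are parameters of `flag_outliers()`. The 0.1 Å figure is used only as
this reporting threshold; it is not treated as a geometric equivalence
between 10° and 0.1 Å.

External rotamer libraries given as plain χ tables are compared via
`library_from_chi_table()`, which realizes each table row as
coordinates by rotating the observed residue's own side chain to the
table's χ values — the observed internal geometry is reused, so the
comparison isolates the χ angles.

## Calibration

`calibrate_weights()` fits the energy weights (optionally a global
torsion-barrier scale) by global-best particle swarm optimisation of
the mean bcRMSD of generated libraries against reference structures.
The PSO uses the standard constriction-equivalent coefficients
(inertia 0.72, cognitive = social = 1.49), clamps positions to bounds,
redraws particles whose objective is non-finite, and is fully
deterministic given its seed. The calibration objective deliberately
uses a coarse 30° scan step: the objective is evaluated hundreds of
times, and weight ordering is insensitive to the grid refinement.
Because only weight *ratios* are identifiable (a common scale cancels
in every acceptance decision), recovery is asserted on the objective
value rather than the raw weight vector.

## The shipped parameter file

No complete parameter set is printed in the literature this model
follows, so the package ships a frozen, self-describing snapshot
(`inst/extdata/parameters.cif`, CIF-style loops) that makes every run
reproducible:

* Pyykkö single-bond covalent radii with uncertainties (C 0.75, N 0.71,
  O 0.63, S 1.03, Se 1.16 Å) and van der Waals radii;
* Amber-style per-element LJ classes (ε, r_min/2; geometric/arithmetic
  combination);
* package-assigned united-atom partial charges with correct per-residue
  net charges (ASP/GLU −1, LYS/ARG +1, others 0) and exact equality on
  symmetric atoms;
* 12-10 H-bond constants (ε 2.0 kcal/mol, r₀ 2.9 Å) and donor/acceptor
  roles;
* torsion terms keyed per (residue, χ index) with an element-pair
  fallback — χ about sp³–sp² bonds uses even periodicity so the χ-flip
  symmetry holds exactly;
* χ definitions, build order and the explicit bond list as *data*, so
  noncanonical residue types (selenocysteine, pyrrolysine) can be added
  without code changes;
* weights w₁..w₄ (default 1.0) and the cutoff radii (2.5/5.0 Å).

Users can override any of it with `--parameters`/`load_parameters()`;
serialization round-trips losslessly.

## Scan defaults and problem sizes

The production default is a 10° step with a 5-unit acceptance window.
Everything in the test suite and the acceptance script runs at a 30°
step on helices of up to 15 residues — grid resolution changes the
density of the accepted set but none of the properties under test
(oracle equivalence, DEE exactness, symmetry, self-consistency), and
these sizes keep the whole suite comfortably interactive. The
self-evaluation checks use a generous window so that every scanned
residue's observed conformation is retained regardless of how far it
sits above its scan minimum.

## What the fixtures do and do not emulate

`build_ideal_residue()`/`build_helix()` construct residues from
standard stereochemistry-table geometry (internally consistent NeRF
placement; aromatic rings as regular hexagons so ring flips are exact
isometries), and `perturb_coordinates()` adds seeded isotropic Gaussian
noise at the scale of crystallographic coordinate error.
`add_clash_probe()` places a carbon exactly at a chosen rotamer's
terminal-atom position to construct guaranteed rejections.

These fixtures exercise every code path without downloads, but they are
idealised: real structures have distorted internal geometry, alternate
conformations, ligands, solvent and lattice contacts, and real
side-chain packing couples neighbouring flexible side chains, which
this scanner (by design) holds rigid. Passing the suite therefore
demonstrates the algorithmic properties — not that the shipped charges
reproduce experimental rotamer frequencies, which would require the
full-PDB benchmarking that is out of scope here.

## Numerical choices

* Angles are degrees at every interface, radians internally; dihedrals
  live in (−180°, 180°] under the IUPAC sign convention.
* The grid starts at −180° and steps upward (half-open range); the
  measured initial χ is evaluated additionally, off-grid.
* Acceptance (`E ≤ E_min + window`) and bond-distance comparisons are
  boundary-inclusive; energy ties in sorting are broken by χ
  lexicographic order so outputs are deterministic.
* Per-pair energy contributions are sorted before summation, making
  totals independent of pair enumeration order.
* A scanned atom landing exactly on an environment atom scores an
  infinite clash inside the scanner (the conformation is rejected);
  the user-facing `pair_energy()` treats zero distance as an error,
  since it indicates duplicated atoms.
* DEE pruning adds a 10⁻¹² slack on the threshold comparison so
  floating-point noise can only make pruning more conservative, never
  less exact.

## Known limitations

* Single-residue scans: pairs of flexible side chains are not
  co-scanned; a neighbour's side chain beyond CB is simply absent from
  the environment.
* Heavy atoms only by default; the shipped charges are united-atom
  style.
* The H-bond term is distance-only (no angular dependence).
* Rotamer probabilities are not estimated; the library reports energies
  and leaves weighting to the consumer.
* PRO is not scanned, and backbone geometry is never relaxed.
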