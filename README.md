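# chiscan

Structure-specific protein side-chain rotamer libraries in R.

## What it does, and for whom

Most side-chain modelling starts from a pre-computed rotamer library —
the statistically frequent χ dihedral angles of a curated PDB subset,
possibly conditioned on backbone φ/ψ. Those averages are fast but blind
to the residue's actual surroundings, and they cannot contain rotamers
the curated subset never saw: strained conformations at active sites,
alternate positions, or side chains of rare residue types.

`chiscan` generates the rotamer library *from the target structure
itself*. For every chi-bearing residue (17 standard types; GLY/ALA have
no χ, PRO's ring is excluded) it

1. builds a cached homogeneous-coordinate transform chain
   p′ = T⁻¹₁ R(Δχ₁) (T₁T₂⁻¹) R(Δχ₂) ⋯ R(Δχ_g) (T_g p)
   mapping any χ vector to side-chain coordinates,
2. collects the rigid environment — main-chain atoms plus CB of
   surrounding residues within the reach radius of CA — with a
   cell-list ("cubing") grid,
3. scans the χ grid depth-first under **dead-end elimination**, scoring
   conformations with the weighted pairwise energy
   E = Σ_pairs Q(r)·(w₁E_LJ + w₂E_C + w₃E_H) + Σ_d w₄E_T
   (Lennard-Jones, Coulomb, 12-10 hydrogen bond under a cosine
   switching cutoff, plus torsion terms), and
4. keeps every conformation within an energy window of the per-residue
   minimum, written out as PDBx/mmCIF with χ values and the full energy
   breakdown per rotamer.

The DEE lower bound is admissible, so the accepted set is *identical*
to exhaustive enumeration — just cheaper. Chemically indistinguishable
flips (ASP χ₂, GLU χ₃, PHE/TYR χ₂) can be scanned over a half range,
and the evaluation layer (`bc_rmsd`, `bc_da`) compares any library —
generated or external χ tables — against observed coordinates with
those symmetries applied. Energy weights can be calibrated against
reference structures by particle swarm optimisation.

Intended users: structural bioinformaticians modelling side chains into
density, benchmarking rotamer libraries, or needing rotamers for
residues and conformations that statistical libraries underrepresent.

## Worked example

```r
library(chiscan)
library(dplyr)

st  <- build_helix(c("ALA", "SER", "LEU", "ASP", "ALA"))   # ideal helix
lib <- generate_library(st, spec = scan_spec(step = 30, window = 5))
glance(lib)
#> # A tibble: 1 × 5
#>   n_residues n_rotamers mean_rotamers  step window
#>        <int>      <int>         <dbl> <dbl>  <dbl>
#> 1          3         78            26    30      5

tidy(lib) |> select(residue, comp_id, chi1, chi2, e_lj, e_total) |> head(8)
#> # A tibble: 8 × 6
#>   residue comp_id  chi1  chi2   e_lj e_total
#>   <chr>   <chr>   <dbl> <dbl>  <dbl>   <dbl>
#> 1 A:2     SER       -90    NA -0.184   5.00
#> 2 A:2     SER       -65    NA  0.319   5.25
#> 3 A:2     SER      -120    NA -0.292   5.54
#> 4 A:2     SER       -60    NA  0.537   5.59
#> 5 A:2     SER      -150    NA -0.261   6.38
#> 6 A:2     SER      -180    NA  0.509   9.57
#> 7 A:3     LEU      -180    60  0.851   0.851
#> 8 A:3     LEU       -65   180  0.858   0.882
```

Each row is one accepted rotamer: its χ angles in degrees, the
unweighted energy-term sums and the weighted total (force-field units;
only differences matter). SER keeps six rotamers within 5 units of its
minimum here; the helix backbone disfavours the eclipsed χ₁ region, and
`A:2 SER −65` is the structure's own (injected) conformation.

Evaluating a library against the structure it came from recovers the
observed conformation exactly — the observed χ vector is always
injected into the scan:

```r
ev <- evaluate_library(st, generate_library(st,
        spec = scan_spec(step = 30, window = 50)))
ev |> select(seq_id, comp_id, n_rotamers, bcrmsd, max_abs_bcda, rmsd_outlier)
#> # A tibble: 3 × 6
#>   seq_id comp_id n_rotamers   bcrmsd max_abs_bcda rmsd_outlier
#>    <int> <chr>        <int>    <dbl>        <dbl> <lgl>
#> 1      2 SER             13 7.69e-16            0 FALSE
#> 2      3 LEU            108 1.13e-15            0 FALSE
#> 3      4 ASP             77 1.26e-15            0 FALSE
```

`bcrmsd` is the best-case RMSD (Å) over the candidate set in the fixed
structure frame (no superposition; candidates share the observed
backbone); `max_abs_bcda` the largest |χ difference| (degrees) of the
selected rotamer; residues with bcRMSD ≥ 0.1 Å would be flagged as
outliers. `autoplot(lib)`, `plot_bcrmsd(ev)` and `autoplot()` on a
calibration fit give the standard ggplot2 views.

### Command line

A thin wrapper around the same functions ships in `inst/exec/chiscan`:

```sh
chiscan generate  --input model.cif --output rotamers.cif --step 10 --window 5
chiscan evaluate  --input model.cif --library rotamers.cif --output report.tsv
chiscan calibrate --references ref1.cif,ref2.cif --out params.cif --seed 1
chiscan fixtures  --kind helix --sequence ALA,SER,ALA --out helix.cif
```

Output libraries are PDBx/mmCIF: one `atom_site` model per rotamer plus
a `_chiscan_rotamer` loop with the residue key, `chi_1..chi_4`
(degrees), `energy_lj/coulomb/hbond/torsion/total` and the accepted
flag — re-readable with `read_library()` or any mmCIF reader. A
machine-readable `.summary.json` (residues scanned, rotamers accepted,
branches pruned, seed) is written alongside every run.

## Package layout

| Area | Files |
|---|---|
| mmCIF I/O | `R/cif-core.R`, `R/mmcif-io.R` |
| Force field & parameters | `R/forcefield.R`, `inst/extdata/parameters.cif` |
| Connectivity & χ topology | `R/topology.R` |
| Transform chains | `R/kinematics.R` |
| Pairwise energy | `R/energy.R` |
| DEE scanner | `R/scanner.R` |
| Evaluation (bcRMSD/bcDA) | `R/evaluation.R` |
| PSO calibration | `R/calibration.R` |
| Ideal-geometry fixtures | `R/fixtures.R` |
| CLI | `R/cli.R`, `inst/exec/chiscan` |

The methods vignette (`vignettes/rotamer-scanning.Rmd`) documents the
model, the shipped parameter snapshot, numerical conventions and known
limitations.
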