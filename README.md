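# pbflex

Per-residue comparison of conformational flexibility between protein
ensembles, built around the **Protein Blocks** structural alphabet.
Written for structural bioinformaticians studying how point mutations —
in the motivating case, disruption of the extra CDR1–CDR3 disulfide
bridge of nanobodies (VHH domains) — shift the equilibrium between
local backbone conformations, without necessarily creating new ones.

Given multi-model PDB ensembles (e.g. MD trajectory snapshots) of two
systems, pbflex:

* assigns every residue of every frame to one of the 16 Protein Blocks
  `a`–`p` by nearest reference window over the dihedrals
  (ψ<sub>i−2</sub>, φ<sub>i−1</sub>, ψ<sub>i−1</sub>, φ<sub>i</sub>,
  ψ<sub>i</sub>, φ<sub>i+1</sub>, ψ<sub>i+1</sub>, φ<sub>i+2</sub>);
* summarizes each position by the equivalent number of blocks
  *N*<sub>eq</sub> = exp(−Σ<sub>x</sub> *f*<sub>x</sub> ln *f*<sub>x</sub>)
  ∈ [1, 16] and by the Cα RMSF after Kabsch superposition;
* compares systems per position by
  ΔPB = Σ<sub>x</sub> |*f*<sub>x</sub>¹ − *f*<sub>x</sub>²| ∈ [0, 2],
  ΔNeq = |*N*<sub>eq</sub>¹ − *N*<sub>eq</sub>²| and signed ΔRMSF
  (variant − wild-type), with CDR/framework region annotation and
  per-region maxima;
* builds disulfide-disrupting truncation mutants (Cys→Ala keeps
  N, CA, C, O, CB; Cys→Gly keeps N, CA, C, O) that provably leave all
  backbone dihedrals untouched;
* ships synthetic-ensemble generators with exactly known conformer
  statistics, so the whole pipeline is testable without trajectories;
* exports everything as tidy tibbles, schema-versioned TSVs, logo-ready
  frequency matrices, FASTA-like PB strings and `ggplot2::autoplot()`
  figures, plus a CLI (`inst/exec/pbflex`) with `mutate`, `profile`,
  `compare` and `simulate` subcommands.

## Worked example

Two synthetic systems whose residues exchange between the helix block
`m` and the strand block `d` with different equilibria (80/20 versus
30/70), 2000 frames each:

```r
library(pbflex)

wt  <- sample_dihedral_ensemble(30, 2000, c(m = 0.8, d = 0.2), seed = 42)
mut <- sample_dihedral_ensemble(30, 2000, c(m = 0.3, d = 0.7), seed = 43)
cmp <- compare_systems(system_profile(mut, label = "mutant"),
                       system_profile(wt,  label = "WT"))
tibble::as_tibble(cmp)[cmp$position %in% 10:12, ]
#> # A tibble: 3 × 9
#>   position region rmsf1 rmsf2 delta_rmsf  neq1  neq2 delta_neq delta_pb
#>      <int> <chr>  <dbl> <dbl>      <dbl> <dbl> <dbl>     <dbl>    <dbl>
#> 1       10 FR1       NA    NA         NA  1.85  1.70     0.146    0.951
#> 2       11 FR1       NA    NA         NA  1.85  1.70     0.146    0.951
#> 3       12 FR1       NA    NA         NA  1.85  1.70     0.146    0.951
```

Read: both systems are nearly two-state (*N*<sub>eq</sub> ≈ 1.7–1.9,
analytic values exp *H* = 1.65 and 1.84), but half of the block mass
has moved (ΔPB ≈ 0.95, analytic L1 distance 1.0) — same conformations,
shifted equilibrium.  RMSF columns are `NA` because dihedral-space
ensembles carry no coordinates.

With coordinates, RMSF joins in.  A 60-residue scaffold whose
"mutant" fluctuates three times harder across positions 23–37 (the
default CDR1 window):

```r
ref <- build_ideal_conformation("helix", 60)
amp_wt <- rep(0.15, 60); amp_mut <- amp_wt; amp_mut[23:37] <- 0.45
wt  <- perturb_coordinates(ref, amp_wt,  800, seed = 1)
mut <- perturb_coordinates(ref, amp_mut, 800, seed = 2)
cmp <- compare_systems(system_profile(mut, label = "mutant"),
                       system_profile(wt,  label = "WT"))
region_summary(cmp)
#> # A tibble: 4 × 5
#>   region n_positions max_delta_pb max_delta_neq max_abs_delta_rmsf
#>   <chr>        <int>        <dbl>         <dbl>              <dbl>
#> 1 CDR1            15       0.25           0.760             0.513
#> 2 CDR2            11       0              0                 0.0111
#> 3 FR1             22       0.0516         0.152             0.0134
#> 4 FR2             12       0.0745         0.180             0.0126
```

The CDR1 ΔRMSF maximum 0.513 Å matches the closed form
(0.45 − 0.15)·√3 ≈ 0.52 Å for isotropic per-axis amplitudes, and the
flexibility difference is confined to the region that was made to
fluctuate.  `autoplot(cmp)` draws the per-position ΔPB/ΔNeq/ΔRMSF
tracks.

Mutants from the command line:

```sh
inst/exec/pbflex mutate  --input wt.pdb --spec C32A,C99G --output mut.pdb --chain A
inst/exec/pbflex compare --input mut.pdb --input2 wt.pdb --out-dir out --chain A
```

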