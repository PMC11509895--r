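---
title: "Comparing conformational flexibility with Protein Blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing conformational flexibility with Protein Blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbflex)
```

## The question pbflex answers

Molecular-dynamics ensembles of two related proteins — typically a
wild-type nanobody (VHH) and point mutants that disrupt a disulfide
bridge — look very similar by global measures, yet can differ in how
often each residue visits its local conformations.  pbflex quantifies
those differences per residue, on two complementary levels:

* **coordinate space**: RMSD per frame and RMSF per residue, both on
  Cα atoms after least-squares rigid superposition;
* **conformation space**: each residue of each frame is assigned to
  one of the 16 **Protein Blocks** (PBs), a structural alphabet over
  backbone dihedrals, and the per-position frequency vectors are
  compared between systems.

The motivating use case is the extra CDR1–CDR3 disulfide bridge carried
by roughly a quarter of VHH domains: truncation mutants (Cys→Ala,
Cys→Gly) of the bridge cysteines are built in silico, simulated, and
compared against the wild type position by position.

## The Protein Block model

A Protein Block is a prototype of local backbone geometry described by
the eight dihedrals of a five-residue window centred on residue $i$:

$$w(i) = \big(\psi_{i-2},\ \varphi_{i-1},\ \psi_{i-1},\ \varphi_i,\ \psi_i,\
\varphi_{i+1},\ \psi_{i+1},\ \varphi_{i+2}\big).$$

The 16 blocks, labelled `a`–`p`, ship with the package as a plain-text
table (`pb_reference()`), frozen by a checksum test.  `m` and `d` are
the regular prototypes (α-helix core and central β-strand); the other
fourteen describe caps and coil motifs and are intrinsically
*transition* patterns — their eight reference angles do not repeat a
single (φ, ψ) pair.

Assignment is nearest-prototype: the dissimilarity between a window and
a prototype is the sum over the eight angle pairs of squared
differences, each wrapped into (−180°, 180°].  The established form of
this score (RMSDA) is a root of the mean; since both are monotone
transformations of the same sum, the package uses the raw sum — the
argmin, all zero/identity properties and all invariances are identical,
and the constant factor is documented here once.  Ties are broken
alphabetically; they have measure zero for real data.  A window
containing an undefined dihedral is unassignable and carries the symbol
`Z`; the two first and two last positions of a chain are always `Z`.

Per position, frequencies $f_x$ of each block $x$ are counts over
assignable frames.  The flexibility summary is the **equivalent number
of blocks**

$$N_{eq} = \exp\Big(-\sum_{x=1}^{16} f_x \ln f_x\Big), \qquad
0 \ln 0 := 0,$$

which ranges from 1 (one conformation only) to 16 (uniform over the
alphabet).  As reading aids, `neq_band()` labels values below 4 *rigid*,
4–6 *flexible*, 6–8 *highly flexible* and 8 or more *disordered*; these
are interpretation bands, not statistical thresholds.  Two systems are
compared by

$$\Delta N_{eq} = |N_{eq}^{(1)} - N_{eq}^{(2)}|, \qquad
\Delta PB = \sum_{x=1}^{16} \big|f_x^{(1)} - f_x^{(2)}\big|,$$

ΔPB being an L1 distance in [0, 2]: 0 means identical block usage, 2
disjoint usage.  ΔPB deliberately complements ΔNeq — two positions can
have equal entropy with entirely different blocks.  RMSF differences are
reported signed, variant minus wild-type.  Positions unobserved in
either system propagate as `NA`, never as 0: absence of evidence is not
evidence of rigidity.

## Coordinate-space measures

Superposition uses the Kabsch algorithm (SVD of the cross-covariance,
determinant forced to +1 so reflections are excluded) on all Cα atoms,
unweighted.  RMSD compares every frame to the first saved frame.  RMSF
is computed about an iteratively refined mean: frames are fitted to the
first frame, averaged, re-fitted to that mean and re-averaged (two
passes by default — standard practice; additional passes change nothing
measurable on well-behaved ensembles), then
$\mathrm{RMSF}_i = \sqrt{\langle |r_i(t) - \langle r_i\rangle|^2\rangle_t}$.

## Mutant construction

`mutate_side_chain_truncation()` builds disulfide-disrupting mutants by
truncation only: Cys→Ala keeps exactly {N, CA, C, O, CB}, Cys→Gly keeps
{N, CA, C, O}; kept atoms retain their coordinates in every frame and
no other residue is touched.  No minimization or rotamer placement is
attempted — the operator feeds a backbone-dihedral pipeline, and the
test suite verifies that φ/ψ, PB strings and Cα metrics are
bit-identical across the mutation.  Residues are identified by PDB
author numbering throughout; the region map (CDR1 23–37, CDR2 50–63,
CDR3 99–105 by default, frameworks filling the complement) is a config
so other numbering schemes or loop definitions can be absorbed without
code changes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| chain-break threshold | 4.5 Å | CA–CA distance beyond which consecutive residues are treated as disconnected; a generous bound on peptide-bond geometry.  Spanning dihedrals become undefined. |
| RMSF refinement passes | 2 | mean-structure refinement iterations before fluctuations. |
| generator noise σ | 10° | per-dihedral wrapped Gaussian noise in the synthetic sampler; small enough that the `m`/`d` basins stay separated, large enough to exercise angle wrapping. |
| global translation σ | 5 Å | random rigid-body translation added per synthetic frame (rotation is uniform on SO(3)); superposition must remove it exactly. |
| region map | VHH CDR bounds above | overridable YAML/JSON. |

## What the synthetic generator emulates — and what it does not

MD trajectories at the microsecond scale are not reproducible at desk
scale, so the package ships generators whose statistics are known
exactly:

* **Dihedral space** (`sample_dihedral_ensemble()`): each position gets
  a conformer distribution over PB labels; per frame a label is drawn
  per position, the label's central (φ, ψ) is taken and wrapped
  Gaussian noise added.  Draws are *comonotonically coupled within a
  frame* (one uniform variate per frame drives every position's
  inverse-CDF draw).  This coupling is a deliberate design choice: a PB
  window spans five residues, so six of its eight angles belong to
  neighbours.  With independent per-position draws a window straddling
  two conformers is usually nearest to a *transition* prototype, not to
  the sampled label — numerically, most mixed-neighbour windows of an
  `m`/`d` mixture misassign.  Coherent frames keep windows homogeneous
  wherever neighbouring positions share a distribution, while leaving
  the per-position marginals exact.
* Exact label recovery through `assign_ensemble()` additionally
  requires mixtures over blocks that re-assign to themselves in a
  homogeneous chain.  Only the regular prototypes `m` and `d` have that
  property — a constant-(φ, ψ) chain is by definition helix- or
  strand-like everywhere, so cap/coil blocks cannot be embedded this
  way.  Recovery tests therefore use `m`/`d` mixtures; the entropy and
  L1 statistics themselves are tested over the full 16-simplex with
  directly constructed frequency vectors.
* **Coordinate space** (`perturb_coordinates()`): harmonic per-residue
  isotropic Gaussian displacement (per-axis σᵢ, applied rigidly to the
  residue's atoms) around a reference built by internal-coordinate
  geometry, plus a random global rigid motion per frame.  The closed
  form $\mathrm{RMSF}_i \to \sigma_i\sqrt{3}$ anchors the recovery
  tests; the random rigid motions verify that superposition removes
  exactly what it should.

What passing these tests shows: the statistics are computed correctly,
the assignment equals an exhaustive search, superposition is exact, and
the estimators converge at the expected binomial rates.  What they do
not show: anything about force fields, solvent, sampling convergence or
the realism of any particular trajectory — the generators make no
attempt at physics, and correlated motions, anharmonicity and
position-dependent anisotropy of real ensembles are deliberately out of
scope.

## Validation scale and numerical choices

The statistical suites run at 10⁴ frames — frequency recovery within
±0.02 (≈4 binomial standard errors at p = 0.5), Neq within 2% of the
analytic exponential entropy, RMSF amplitude recovery within 5% on a
100-residue scaffold where the fit absorbs under 1% of a single
residue's variance.  Smaller-n sanity versions with correspondingly
wider binomial bounds run in the unit suites.

Angles are wrapped into (−180°, 180] with 180° kept positive; torsion
signs follow the convention shared by Biopython and mdtraj (checked
against bio3d in the tests).  Near-collinear torsion quadruples return
`NA` rather than a value.  Degenerate (rank-deficient) point sets are
rejected by the superposition.  The PB table checksum pins the shipped
reference angles.  Frequencies must arrive normalized — `neq()` and
`delta_pb()` refuse to rescale silently.

## Replicate pooling

When an ensemble concatenates simulation replicates, PB counts are
pooled across all frames before normalization (the frequencies of the
union of frames), matching the design where several production runs
jointly represent one system.  `run_profile(replicates = ...)`
additionally emits per-replicate frequency tables so between-replicate
dispersion can be inspected; the headline profiles always use pooled
counts.

## Known limitations

* PDB is the only trajectory format; XTC/DCD users must convert first.
* No IMGT renumbering; author numbering everywhere, with the region
  map as the adapter.
* ΔPB is reported raw, without significance machinery — the comparison
  is descriptive, and mapping ΔPB to a "percent different" gloss is
  left to the reader (ΔPB/2 is an upper bound on the moved mass).
* Mutant construction is truncation-only; it cannot create side chains
  or repack neighbours.
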