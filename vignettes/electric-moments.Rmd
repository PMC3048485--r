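---
title: "Methods: Cα-based electric moments and RBP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Cα-based electric moments and RBP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpmoments)
```

## The model and its assumptions

`rbpmoments` treats a protein chain as a set of unit point charges
placed at Cα positions: +1 e on Lys and Arg, −1 e on Asp and Glu, 0 on
everything else. This is a deliberately coarse model. Its assumptions
are:

- **Side chains carry no extra information at this resolution.** The
  charge sits at the Cα rather than at the charged group, displacing it
  by ~2–7 Å. For whole-chain moments of 50+ residues this displacement
  largely averages out, and it makes the method applicable to Cα-only
  and modelled structures.
- **Formal integer charges.** No pKa or environment effects; His is
  neutral by default. The `his_positive` scheme is the opposite extreme,
  and `his_sensitivity()` quantifies how little the choice matters
  (correlations near 1 across a structure set). Terminal charges
  (N/C-termini) are not modelled: they contribute one +1/−1 pair per
  chain and are not identifiable from Cα records in a robust way.
- **Moments about the geometric centre.** The reference point R₀ is the
  unweighted mean of *all* Cα positions, charged and neutral. The same
  reference is used for the quadrupole sum. For chains with nonzero net
  charge the dipole depends on this choice; using the geometric centre
  makes it a measure of charge asymmetry relative to the body of the
  protein.

The five descriptors are: net charge per residue `q` (signed), dipole
magnitude per residue `p` in Debye, and the three signed eigenvalues
`Q1 ≥ Q2 ≥ Q3` of the traceless quadrupole tensor, per residue, in
e·Å².

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Debye conversion | 4.80321 | D per e·Å | fixed physical constant (e·Å → D) |
| length normalisation N | residues with a Cα | — | the only chain length observable from the coordinates actually read; SEQRES lengths can differ by disordered termini, so reproduction of published per-residue values is expected only to within a few percent |
| contact cutoff | 4.5 | Å | heavy-atom/heavy-atom distance for protein–RNA contact counting; a common interface criterion. The value used in the original corpus curation is not documented, so this default is our choice and is configurable |
| RNA chain rule | >50% | — | fraction of polymer residues named A/C/G/U/I; DNA names (DA/DC/DG/DT) never count |
| His mode | neutral | — | see above |

## Reading PDB files

Only the first `MODEL` of an entry is read (the standard convention for
“the structure” of an NMR ensemble). `HETATM` records — waters, metals,
ligands — are always ignored. Alternate locations keep the
highest-occupancy conformer, ties broken by file order. Residue
identity is (chain, author number, insertion code); the `residue_range`
argument compares author numbers and ignores insertion codes, which is
what domain definitions like “residues 1–28” mean in practice. Residues
lacking a Cα are skipped and counted in a warning tally, so that
(records read) + (tally) always equals the number of amino-acid
residues present. Residue names outside the 20 standard amino acids
(MSE, other modified residues, unknown ligand codes in ATOM records)
are kept as residues and scored 0 by the charge table.

## Bound/unbound distance (pair statistics)

The per-class distance between complexed and free forms of the same
protein is the RMS difference

ED(X) = sqrt( (1/N) Σ (X_bound − X_free)² )

over the N pairs of a class. The 1/N inside the root makes ED a
per-pair RMS rather than a growing ℓ2 norm: recomputing from the
shipped table of published rRNA dipole pairs gives 0.76, consistent
(after rounding) with the published per-class value 0.7, whereas the
unnormalised sum would give 2.15. The analogous quadrupole distances
are dominated by single outlier pairs (one ribosomal protein pair
changes Q1 by 12.6 e·Å²) and published per-class Q values are not
reproducible from the rounded table entries under any simple variant;
the package therefore reports ED(Q1) as computed and the tests do not
gate on it.

Group differences use the Welch (unequal-variance) two-tailed t-test by
default — the default of R's `t.test()`, which is also what an analysis
done in R most plausibly used — with `pooled = TRUE` available for the
classical equal-variance form. No multiple-testing correction is
applied; p-values are reported raw.

The conservation measure for a sequence cluster is the noise-to-signal
ratio |sd/mean| of a descriptor across cluster members; it is
scale-invariant and undefined for zero-mean clusters (an error, not a
silent NaN).

## Classifier

Architecture 5–3–1: five inputs, one hidden layer of 3 sigmoid units,
sigmoid output read as P(positive class). Features are z-scored with
statistics of the training fold only. Training is full-batch gradient
descent on the **summed** cross-entropy, learning rate 0.05, 500
epochs, weights initialised uniformly in (−0.5, 0.5) from a fixed seed.

Two of these choices deserve justification. First, the sum (rather than
mean) loss convention: it is the aggregate equivalent of classical
per-pattern backprop with learning rate 0.05, and at these sample sizes
it trains to convergence within 500 epochs. Descending the *mean* loss
with the same rate leaves the network close to its intercept solution;
the leave-one-out scores are then dominated by each training fold's
class base rate, which is deterministically anti-correlated with the
held-out label and drives the null (permuted-label) AUC to ~0.24
instead of 0.5. The summed-loss protocol restores an unbiased null
(AUC ≈ 0.46 on the test configuration) without changing the stated
rate/epoch values. Second, no resampling for class imbalance: AUC, the
headline metric, is insensitive to class ratios.

Evaluation is a strict jackknife: sample *i* is scored by a network
trained on the other n−1 samples, including refitting the
standardisation statistics, so no information about the held-out sample
leaks into its score (the test suite asserts this by refitting folds
independently). AUC is computed by the Mann–Whitney identity (ties
count one half), which equals trapezoidal integration over all distinct
score cutoffs. Thresholded metrics are reported at the lowest observed
score cutoff maximising the F-measure `2pr/(p+r)` (the harmonic — not
geometric — mean of precision and recall), with samples called positive
at score ≥ cutoff.

## Synthetic data: what it does and does not establish

The generator produces three kinds of ground-truthed inputs:

- `make_structure()`: point-charge configurations (charges in
  {−1, 0, +1}, encoded LYS/GLU/GLY) written as valid Cα-only PDB files.
  Coordinates are quantised to the PDB 1e-3 Å grid *before* the
  expected moments are computed, by a literal term-by-term summation
  that shares no code with the vectorised implementation — so a green
  round-trip test certifies the whole read → charge → moment stack to
  1e-9.
- `make_pairs()`: bound/unbound pairs from a base configuration plus
  isotropic Gaussian coordinate jitter; ED is exactly 0 at zero jitter
  and grows with it.
- `make_features()`: two-class isotropic Gaussian feature tables. A
  single informative dimension with unit variance and mean separation Δ
  has closed-form optimal AUC Φ(Δ/√2) — Δ=2 gives 0.921 — which the
  jackknifed network should approach at large n. Layout helper spacing
  (3.8 Å steps) is cosmetic.

What the synthetic world does **not** emulate: real residue-composition
statistics (charge fractions, chain-length distributions), correlated
descriptor structure (in real proteins q, p and Q1 are strongly
dependent), class imbalance of realistic corpora, disordered/missing
residues, or conformational change with physical structure. A green
classifier test therefore establishes the correctness of the protocol
and its statistical behaviour, not the published corpus AUCs (those
require the original 160 + 2441 chain data sets, which cannot be
rebuilt offline).

All generators take a mandatory seed and save/restore the caller's RNG
state; nothing in the package reads or mutates the global stream as a
side effect.

## Numerical choices

- Symmetry of the quadrupole tensor is enforced exactly
  (`(M + Mᵀ)/2`) before eigendecomposition; `eigen(symmetric = TRUE)`
  then guarantees real eigenvalues, reported sorted decreasing by
  signed value. Tracelessness implies Q1 ≥ 0; the invariant
  |Q1+Q2+Q3| ≤ 1e-9·max(|Q1|, 1) is tested on 1000 random inputs.
- Degenerate eigenvalues are simply reported in sorted order; no
  orientation (eigenvector) claims are made anywhere.
- CLI floating-point output is fixed at 6 significant digits so
  identical inputs and seeds give byte-identical files.
- PDB coordinates are fixed-width `%8.3f`; writing rejects coordinates
  outside (−999.999, 9999.999) rather than corrupting columns.

## Known limitations

- mmCIF, biological assemblies, symmetry mates and occupancy-weighted
  altloc averaging are unsupported.
- The published corpus statistics (class-wise moment tables, corpus
  AUCs) are not reproducible without bulk structure downloads and
  era-specific functional annotations; the package reproduces the
  desk-scale published quantities (the rRNA pair distance, the worked
  single-structure examples given network access) and verifies
  everything else by construction.
- The length-normalisation convention (resolved residues vs full
  sequence length) is inferred; per-residue values of published tables
  are matched to within a few percent, not exactly.
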