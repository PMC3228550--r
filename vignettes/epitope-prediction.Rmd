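---
title: "Predicting conformational B-cell epitopes with thick surface patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conformational B-cell epitopes with thick surface patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipatch)
```

## The problem

Antibodies recognise antigens at B-cell epitopes. Most epitopes are
conformational: their residues are scattered along the sequence but cluster
in space on the folded antigen's surface. Given only an antigen 3D
structure, epipatch scores every surface residue for its propensity to be
part of an epitope. When an antigen–antibody complex is available it also
derives the ground-truth labels used for training: an antigen residue is an
epitope residue when the minimal Euclidean distance between any of its
heavy (non-hydrogen) atoms and any antibody heavy atom is strictly below
4 Å. That minimal heavy-atom distance is the single residue–residue metric
used throughout the package, for labelling, patch construction and the
distance feature alike.

## The model

### Thick surface patches

A residue is a **surface residue** when its relative accessible surface
area (RASA) exceeds 5 % (strictly); everything else is interior. The local
spatial context of a surface residue is its **patch**: the residue itself
plus its $n-1$ spatially nearest antigen residues. In the classical
*surface patch* only surface residues are eligible neighbours. The *thick
surface patch* draws neighbours from all residues: interior residues cannot
be epitopes themselves, but they shape the packing under an epitope site,
and including them consistently improves discrimination. The package
supports both modes; `thick` with $n = 20$ is the default, and sizes
12–20 are routinely useful. On the synthetic globules used in the test
suite, 20-residue thick patches typically contain about 4–7 interior
residues, matching what compact single-domain antigens show.

Neighbour ranking uses the minimal heavy-atom distance, with ties broken by
residue file order so a patch — and hence its feature vector — is a pure,
reproducible function of the input structure.

### Adjacent residue distance (ARD)

Epitope patches are systematically *looser* than non-epitope patches: the
mean distance between a patch's neighbours and its centre is larger when
the centre is an epitope residue. The ARD feature encodes each neighbour's
proximity as a normalised inverse distance,

$$S(x_i) = \frac{p_i}{\sum_j p_j}, \qquad p_i = \frac{1}{d_i},$$

where $d_i$ is the minimal heavy-atom distance of neighbour $x_i$ to the
central residue. The weights sum to one over the neighbours and decrease
strictly with distance, so near neighbours dominate. The central residue's
own slot is a zero sentinel: the formula is defined over adjacent residues
and $1/d$ is singular at $d = 0$; the sentinel keeps the vector length at
$7n$ without disturbing the normalisation.

### Per-residue descriptors

Each patch residue carries 7 values, concatenated centre-first and then in
ascending-distance order into a $7 \times n$ vector:

| slot | meaning | range |
|---|---|---|
| rasa | SASA / fully-exposed reference area of the residue type | 0 – ~1.2 |
| cons | conservation: $|M_{ir}-B_{rr}|$ if $M_{ir} < B_{rr}$, else 0 | ≥ 0 |
| ard | $S(x_i)$ as above (0 for the centre) | 0 – 1 |
| comp | fraction of the patch sharing this residue's amino-acid type | 1/n – 1 |
| ss_helix, ss_sheet, ss_coil | one-hot 3-state secondary structure | {0,1} |

$M_{ir}$ is the PSI-BLAST PSSM score of position $i$ for its own residue
type $r$ and $B_{rr}$ the BLOSUM62 diagonal; a position scoring below its
self-substitution baseline is un-conserved and receives a positive score.
PSSMs are inputs (profiles from an iterated search), read from the classic
ASCII matrix format; the package never runs BLAST.

The amino-acid composition deserves a note: it is defined patch-wide (the
percentage of each type in the patch) yet must occupy one slot per residue.
We resolve this as "the fraction of the patch sharing this residue's
type" — the only one-dimensional per-residue reading consistent with both
constraints. A 20-dimensional patch-level composition appended once is a
straightforward alternative, but it changes the vector contract and is not
used by default.

A per-residue **contact number** (count of Cα atoms within 10 Å) can be
appended as an 8th slot for comparison experiments; it is off by default
because its information largely duplicates what the thick patch already
encodes.

### Solvent accessibility

SASA is computed by the Shrake–Rupley method: a deterministic golden-spiral
lattice (960 points by default) on each atom's probe-expanded sphere
(probe 1.4 Å, fixed built-in van der Waals radii), counting points outside
all neighbouring expanded spheres. The lattice is expressed in a
molecule-intrinsic frame (principal axes with an odd-moment sign
convention), which makes the estimate invariant under rigid-body motion of
the input for any generic structure — a property the test suite asserts at
1e-6 relative tolerance. At 960 points, exposed residues agree with a
4000-point reference within 3 %; near-buried residues (a few Å², at the
lattice resolution limit) are held to 3 % of the fully-exposed reference
instead, which is the scale at which they enter RASA. The fully-exposed
reference areas are the Gly-X-Gly theoretical maxima of Tien et al.
(2013), shipped as an overridable table since published RASA values vary
slightly with the reference chosen.

Antigen accessibility is always computed on the antigen chains alone:
the antibody must never bury the epitope it defines.

Secondary structure comes from a DSSP file when one is supplied (8-state
codes collapsed H/G/I → helix, E/B → sheet, rest → coil). Without one, a
documented fallback assigns states from backbone φ/ψ dihedral basins with
minimal run lengths (3 for helix, 2 for sheet); it is an approximation,
announced with a message, and never used silently when a DSSP file is
present.

### The imbalanced-class ensemble

Epitope residues are a small minority of surface residues. A single
classifier trained on the raw data drowns the positive class, so the
package trains a committee: the negatives $A^-$ are sampled `n_sub` times
down to the size of the positives $A^+$ (without replacement within a
subset, independently across subsets), each balanced subset trains one
random forest, and a new instance receives one binary vote per forest. The
final call is positive when votes reach the cutoff, by default half the
sub-classifiers, with a tie at exactly half counting as positive. The vote
fraction `votes/n_sub` is a cutoff-agnostic score in [0, 1]; sweeping the
cutoff over `0..n_sub+1` traces the ROC curve, whose trapezoidal area
equals the Mann–Whitney rank statistic with half credit for ties (the test
suite verifies this identity against an independent rank oracle).

Defaults follow the Weka-era random-forest defaults the method was
developed with: 10 trees per forest and $\lfloor\log_2 m\rfloor + 1$
candidate features per split. `n_sub` defaults to
`round(|A⁻|/|A⁺|)`, so the subsets jointly cover roughly the whole
negative set; it is freely configurable, as the committee size is nowhere
canonically fixed. One master seed spawns per-subset seeds, making
training and prediction bit-reproducible.

### Evaluation

Cross-validation is leave-one-*structure*-out: every fold trains on the
pooled instances of all other structures and predicts the held-out one, so
no residue of a test antigen ever influences its own prediction. The
primary summary is the unweighted mean of per-structure AUCs; a
pooled-residue AUC is reported alongside because the two conventions can
differ and the per-structure convention is only implicit in the protocol.
Confusion metrics (SN, SP, ACC, precision, F) are evaluated at the
half-votes cutoff, and any metric with a zero denominator is reported as
undefined (`NA`), never as 0. A held-out structure with single-class labels
is skipped for AUC with a warning.

The distance analysis behind ARD is reproduced by
`patch_distance_statistics()`: per central amino-acid type, the mean
adjacent distance of epitope vs non-epitope patches, and per neighbour rank
$k$, the mean distance of the $k$th nearest neighbour per class — each
compared with a paired t-test implemented from its closed form (trivially
verifiable; the suite checks it against `stats::t.test`). A statistical
caveat matters at small scale: the by-$k$ pairing reuses the same patches
in all $n-1$ pairs, so its differences are strongly correlated and the
test is anti-conservative when patches are few; the by-type pairing uses
disjoint patch sets per pair and stays calibrated. Both are reported, and
the calibrated by-type p-value is the one the package's own acceptance
checks rely on.

## The synthetic data generator

Real benchmark complexes and their PSSMs cannot ship with the package, so
every claim the test suite makes is exercised on synthetic fixtures built
by `generate_complex()`:

* a self-avoiding random walk confined to a sphere gives a pseudo-globular
  antigen chain (60 residues, 12.5 Å radius by default — chosen so that
  20-residue thick patches contain the realistic 4–7 interior residues);
  residues are five heavy atoms (N, CA, C, O and a pseudo-CB) in random
  orientations, enough for minimal-distance semantics without side-chain
  modelling;
* a cluster of `contact_size` outer-shell residues is designated the
  epitope, and an antibody chain is placed so that exactly those residues
  fall strictly within 4 Å (each designated residue gets a partner residue
  positioned by binary search along the outward normal; non-designated
  residues are kept at ≥ 4.25 Å). The construction is verified against the
  package's own labelling oracle on the coordinates as written at PDB
  precision, and retried if verification fails;
* the `shift` parameter thins the residue density around the epitope site
  by a radial expansion about the site centroid: every residue's distance
  to that centroid grows by `shift` Å, which inflates adjacent distances
  strongly near the site and negligibly far from it, and provably never
  decreases any pairwise distance — so the epitope-vs-non-epitope distance
  gap is monotone in `shift` by construction;
* matching DSSP-format files (a fixed helix/coil/sheet truth pattern) and
  PSI-BLAST ASCII PSSMs are emitted so the readers are exercised end to
  end. `simulate_epitope_dataset()` additionally plants a conservation
  signal: epitope positions are mostly non-conserved, others mostly
  conserved, with a 15 % contradiction rate.

What the generator does **not** emulate: real backbone geometry, side
chains, hydrogen-bonded secondary structure consistent with the emitted
DSSP truth, sequence-dependent packing, or the label noise of real epitope
annotations. Passing tests therefore demonstrate that the pipeline's
computations are correct and that it recovers signals of the planted kind —
not that the shipped defaults reach any particular accuracy on real
antigens, which depends on real structures and profiles.

## Numerical choices and degenerate inputs

* Strict inequalities at both classification boundaries (4.0 Å contact,
  5 % RASA): a residue at exactly the threshold is non-epitope/interior.
* Alternate locations: the highest-occupancy conformer per atom wins, ties
  by altloc identifier; multi-model entries use model 1 only.
* MSE (selenomethionine) is retained and remapped to MET; other
  non-standard residues are skipped with a warning; waters and ligands are
  excluded everywhere.
* Duplicate coordinates (a zero adjacent distance) are a hard error rather
  than an infinite ARD weight.
* Patch ties and subset sampling are seed-deterministic; identical inputs
  give bit-identical feature vectors, votes and reports.
* Label permutation for null runs happens after feature construction, so
  a null run shares every feature with its signal counterpart and differs
  only in the response.

## Scale of the shipped experiments

The test suite and the acceptance script run entirely on synthetic data:
8-structure datasets (about 430 surface-residue instances) for
cross-validation, 20 label permutations for the null band, 12-structure
pools (about 630 patches) for the distance statistics, and 20-seed
batteries for the oracle equivalences. These sizes give stable statistics
for every property checked while keeping a full run in a few minutes on a
single CPU.

## Known limitations

* The fallback secondary-structure assigner is a coarse dihedral heuristic;
  supply DSSP files for published-quality annotations.
* Unbound-structure evaluation requires an external label annotation file;
  the package does not transfer labels from a complex onto unbound
  coordinates.
* The SASA lattice orientation is ambiguous for exactly symmetric atom
  arrangements (a measure-zero case for real molecules).
* Feature semantics assume single-conformer, heavy-atom-complete
  residues; severely incomplete residues degrade distances silently.
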