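---
title: "Comparing acid-stable proteins with their neutral-cytoplasm orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing acid-stable proteins with their neutral-cytoplasm orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidostab)
```

## The problem

Most proteins denature quickly at low pH, which is a standing obstacle for
oral delivery of protein drugs and for enzymes used in acidic industrial
processes. A few acidophilic bacteria maintain an acidic cytoplasm, so their
cytoplasmic proteins are presumably acid-stable (we call them AP); proteins
from acidophiles whose cytoplasm is kept near-neutral by pH homeostasis make
natural non-acid-stable controls (NP). Comparing AP proteins with their NP
orthologs — essentially mutants separated by many substitutions but sharing
function and localization — isolates sequence signals associated with
acidostability.

`acidostab` implements that comparative machinery end to end:

1. an ortholog-pairing pipeline (reciprocal best hits plus conservative
   filters),
2. an 889-entry sequence feature catalogue,
3. a directional 20×20 substitution propensity matrix with Fisher exact
   bias calls,
4. per-residue composition comparisons (paired and unpaired t-tests),
5. a linear relative-difference scoring function trained by hill climbing,
6. Random-Forest Gini-importance feature ranking with pair-aware
   cross-validation, and
7. a synthetic ortholog-pair generator so all of the above is testable
   without downloads.

## Ortholog pairing

Candidate pairs are reciprocal best BLAST hits (each sequence the other's
best match) with both e-values below 1e-10. Hits can be ingested from
standard 12-column BLAST tabular files; absent those, the package aligns
all-against-all with its own global Needleman–Wunsch aligner (BLOSUM62,
affine gaps 11/1 — BLAST's default protein scoring) and ranks hits by
alignment score. Pairs must then satisfy:

* absolute length difference strictly less than 5% of the shorter sequence,
* similarity strictly greater than 30% (BLAST percent positives when
  available, otherwise alignment percent identity — a documented
  discrepancy, since percent positives are not part of the 12-column
  dialect),
* neither member transmembrane (ids supplied externally, e.g. from TMHMM),
* redundancy removed by blastclust-style single-linkage clustering
  (identity ≥ 0.25 with ≥ 0.5 alignment coverage of both sequences links
  two sequences; one pair is kept per connected cluster — the one with the
  smallest e-value, ties broken by lexically smallest AP id, a convention
  the original procedure leaves unstated),
* final lengths strictly inside (50, 600) residues.

The "difference of two sequences" rule is read as raw length difference
(not alignment length), and the identity denominator is aligned
(non-gap-pair) columns; both are configurable because the source procedure
does not state its conventions.

## The feature catalogue

Each protein is encoded by 889 named features: sequence length; amino-acid
counts and compositions (40); dipeptide counts and compositions (800);
charge features (8); small/tiny/aromatic/aliphatic/hydrophobic/polar
category counts and fractions (12); hydrogen-bond-capable side chains (2);
sulfur atoms (1); mean per-residue maximum solvent-accessible surface area
(1); isoelectric point and residue-averaged pI (2); instability index and
class (2); aliphatic index (1); GRAVY (1); plus 18 placeholders for
predictor-derived properties (secondary structure, burial, disorder, RSA,
Z-fit) that are ingested from external tools, never computed here.

Counts are prefixed `c_`, length-normalized values `x_` (denominator L, or
L−1 for dipeptides). Ambiguity codes (`X B Z U J O`) are skipped in
numerators but count toward L, keeping compositions comparable without
discarding records.

Only the small (T, D), tiny (G, A, S, P) and aromatic (F, H, Y, W) sets are
fixed by the source study; the remaining memberships are this package's
choices, kept in one editable table (`residue_sets()`): aliphatic
{A,I,L,V}, hydrophobic {A,C,F,I,L,M,V,W}, polar {D,E,H,K,N,Q,R,S,T,Y},
positive {K,R}, negative {D,E}, hydrogen-bond capable
{D,E,H,K,N,Q,R,S,T,W,Y}. Net charge is count(K,R) − count(D,E) with His
excluded (the common pH-7 convention).

Numerical notes: pI is found by bisection on the Henderson–Hasselbalch
net-charge curve with the Bjellqvist pKa set, without residue-specific
terminal adjustments (a deliberate simplification; values match ProtParam
unless the terminal residue carries such an adjustment); the instability
index is `10/L` times the sum of published dipeptide instability weights,
class unstable above 40; the max-ASA scale bundled is the theoretical
per-residue maxima of Tien et al. (2013) and is replaceable via the
`max_asa` argument, since published scales differ by a few percent and the
original study does not print the one it used.

## The substitution propensity matrix

Every aligned, non-gap, standard-residue column of every pair increments
`counts[ap_residue, np_residue]`; `counts[r, c]` is therefore the forward
(NP→AP) substitution c→r. The displayed ratio divides each cell by its
transpose (half-up at two decimals), so values above 1 mark forward-favored
substitutions. On the bundled published count matrix the package reproduces
all 380 printed ratio cells exactly.

Bias significance uses a two-sided Fisher exact test per unordered residue
pair at p < 1e-10. The source study does not state its 2×2 construction,
and this matters. We evaluated the candidates on the bundled counts:

* comparing the two directed counts against equal total-substitution
  margins can never reach p < 1e-10 for counts like 488 vs 420, yet such
  cells are marked significant in the published matrix — 0 calls result;
* a per-cell margins (independence) test produces asymmetric calls far in
  excess of the published totals;
* comparing each directed count against the NP-side abundance of its
  source residue yields 69 forward / 69 reverse calls;
* comparing each directed count against the AP-side abundance of its
  target residue — "is gaining r from c more common than gaining c from r,
  relative to how abundant r and c are?" — yields 48 significant pairs
  (96 cells, 48 forward / 48 reverse) and recovers 40 of the 44 unordered
  pairs marked significant in the published matrix, by far the closest
  agreement.

The last construction (`"ap_conditional"`) is the shipped default; the
others remain selectable. The published totals themselves (81 cells: 43
forward, 38 reverse) cannot be reproduced exactly from the printed
aggregate counts by any of these tests — they are also internally
asymmetric (37 pairs marked in both cells, 7 in only one), which no
symmetric pair test can produce — so the corresponding acceptance check is
left failing by design and the nearest construction's totals are reported.

Composition comparisons run two-sided paired and unpaired (Welch) t-tests
per residue on the `x_` composition features across pairs. Zero-variance
paired differences are flagged degenerate with p = 1 when all differences
are zero and p = 0 otherwise.

## The scoring function

For a pair of feature vectors the bounded relative difference is

  Δx_i = (x_i(seq1) − x_i(seq2)) / (x_i(seq1) + x_i(seq2)),

zero when both values are zero; it is sign-symmetric and lies in [−1, 1]
for non-negative features. Plain and reference-normalized differences are
available as alternative modes, and results always carry the mode used.
The pair score is the weighted sum over the ten most discriminative
features (x_K, x_small, x_T, x_tiny, x_aliphatic, x_aromatic, x_I, x_LQ,
x_Q, x_Y); a positive score predicts that the first sequence is the AP
member. The published weight vector (0.68, 0.75, 0.90, 0.58, −0.97, −0.74,
−0.96, −0.04, −0.01, −0.53) ships as the default. Scores are exactly
antisymmetric under pair reversal, and a score of exactly zero counts as
incorrect (a conservative tie rule; the source does not state one).

Weights are trained by hill climbing under |w_i| ≤ 1: random start, a
proposed perturbation, and acceptance only when the number of pairs with
strictly positive score increases. The proposal ships as a joint uniform
perturbation of all weights (step half-width 0.1, configurable). A
single-coordinate proposal is available (`coordinate = TRUE`) but is not
the default for a structural reason: with strict-increase acceptance there
are only twenty single-coordinate move directions, and on weakly separable
data the search provably locks in coarse local optima (exhaustive search
over all such moves stalls near 53/100 correct on separable synthetic
deltas), whereas joint perturbation solves the same instances. The fit is
restarted (default 5 times) and the element-wise average of the
per-restart optima is returned, with full traces for monotonicity checks.
The iteration budget is configurable; the package default is 1e5, which
suffices for the 10-weight problems here.

Evaluation treats each oriented pair as one positive case and its reversal
as one negative case, so accuracy = (TP+TN)/(TP+TN+FP+FN) with TP = TN by
antisymmetry. ROC/AUC uses the rank-sum (Mann–Whitney) formulation with
ties counted 0.5 (verified against trapezoidal integration of the
empirical curve); negatives for the score ROC are the reversed pairs, a
construction the source leaves undefined.

## Random-Forest ranking

Classification is per sequence (AP vs NP), with folds split by ortholog
pair so the two members of a pair never straddle a train/test boundary.
Per fold a `randomForest` of 5000 trees (default) is fitted on the
training portion; mean-decrease-in-Gini importances are averaged across
folds and features ranked by the mean. Gini impurity is 1 − Σ p_k².
Subset evaluation pools out-of-fold predicted probabilities and reports
accuracy and AUC. A simple backward-elimination variant (drop the
lowest-importance 20% per round, keep the subset with best out-of-fold
AUC) is provided for feature-set selection; it deliberately does not
reproduce the varSelRF algorithm and is labeled non-equivalent.

## The synthetic generator

`generate_pairs()` emulates the statistical structure of real AP–NP
ortholog sets. NP sequences are drawn i.i.d. from a background
composition; defaults are the observed mean NP composition of real
ortholog sets, normalized. The AP mate redraws each site with probability
`substitution_rate` from the background reweighted by a directional bias
map (the source residue excluded, so every substitution event changes the
residue); optional single-residue indels with geometric extension come
after substitutions and are off by default. Defaults mirror the real study
conditions: 393 pairs, lengths uniform in the open (50, 600) window, and
rate 0.3, giving roughly 70% identity — inside the 30–90% identity range
of real pairs. The truth record carries the exact alignment and realized
substitution counts, which the test suite verifies are self-consistent
with the emitted sequences.

Two model properties matter when interpreting tests. First, the mutation
model is site-independent with one global rate — no rate heterogeneity,
domain structure, or phylogeny — so passing tests demonstrate the
machinery recovers planted signals, not that real proteomes behave this
way. Second, a bias entry (from, to, multiplier) redirects where a residue
mutates to; it does not change how often the source residue mutates, so
depleting a residue in AP requires suppressing it as a target across
sources (the tests construct such maps explicitly).

`generate_separable_deltas()` plants a known weight vector and rejection
samples delta vectors scoring at least a chosen margin before Gaussian
noise, providing a controlled workload for the trainer.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on bundled printed
tables and synthetic data: 50–100 synthetic pairs of length 150–300 for
scoring checks, 10 seeds × 100 pairs for trainer and bias-recovery
properties, and forests of a few hundred trees on 60-row matrices —
sizes chosen so the full suite completes in about a minute while leaving
comfortable statistical margins. All randomness flows from explicit seeds;
identical invocations are bit-reproducible.

## Known limitations

* BLAST, TMHMM, NetSurfP and disEMBL are never run; their outputs are
  ingested. The 18 predictor-derived features stay `NA` unless supplied.
* The internal-aligner pairing path ranks hits by alignment score, not
  e-value, so the 1e-10 threshold applies only when hit files are given.
* The published bias-call totals are not exactly reproducible from the
  printed aggregate counts (see above); the default construction is the
  documented nearest candidate.
* The pI omits residue-specific terminal pKa adjustments.
* Full-scale reproduction of the published accuracies requires the
  original proteomes and supplementary sequence sets, which are not
  bundled; the package verifies the machinery on synthetic analogues
  instead.
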