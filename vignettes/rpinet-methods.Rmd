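---
title: "Sequence-composition models of RNA-protein interaction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-composition models of RNA-protein interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpinet)
```

## The model and its assumptions

`rpinet` treats partner prediction — does this RNA bind this protein? —
as binary classification of a fixed-length composition vector. The core
assumption is that binding propensity leaves a footprint in short-range
sequence composition: which kinds of residues cluster in the protein,
and which 4-mers recur in the RNA. No positional information, structure,
or co-evolution enters the model; two sequences with the same k-mer
spectra are indistinguishable to it.

A protein is reduced to a 7-letter alphabet before counting. The seven
residue classes — {A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K},
{D,E}, {C} — group amino acids by dipole moment and side-chain volume,
so a triad such as {I,L,F,P}{A,G,V}{R,K} stands for all 24 concrete
triplets (IAR, IAK, IGR, ...) that share a hydrophobic-small-basic
physicochemical profile; `enumerate_triplets()` expands any class. The
7³ = 343 triad frequencies and the 4⁴ = 256 RNA 4-mer frequencies are
each normalized to sum to 1 and concatenated, protein part first, into
the 599-feature pair vector. The class order above is fixed: it defines
the feature indexing (triad (g₁,g₂,g₃) ↦ g₁·49 + g₂·7 + g₃, 0-based)
and must never be permuted once models exist.

Two classifier families are offered because they fail differently: a
random forest (20 trees, 10 candidate features per split; probability =
fraction of trees voting positive) is robust to the many zero features
of short sequences, while the SVM with a normalized polynomial kernel of
order 2 captures smooth pairwise feature interactions. SVM margins are
mapped to probabilities by Platt scaling — a logistic model fitted to
margins obtained by internal 3-fold cross-validation, so the calibrator
never sees margins of points the SVM trained on. A pair is called
interacting at probability ≥ 0.50, inclusive at the boundary.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rf_trees` | 20 | forest size for prediction; 500 is the large-ensemble setting used for stable feature importance |
| `rf_features_per_split` | 10 | candidate features per split; fallback `floor(log2(p)) + 1` when unset |
| `svm_c` | 1.0 | soft-margin cost |
| `svm_tolerance` | 0.001 | SMO convergence tolerance |
| `svm_kernel_degree` | 2 | polynomial order of the normalized kernel |
| `decision_threshold` | 0.50 | probability at or above which an edge is called |
| `min_protein_length` | 26 | dataset filter: proteins longer than 25 residues |
| `min_rna_length` | 15 | dataset filter: RNAs of at least 15 nt |
| `identity_threshold` | 0.30 | pairwise identity at or above which two sequences count as similar |

`svm_epsilon` (1e-12) is carried in the configuration for fidelity with
the SMO implementation the defaults were tuned on, but has no equivalent
control in the kernlab solver used here; it is inert.

## Dataset construction rules

Benchmark construction from a list of positive pairs applies, in order:

1. **Length filter** — keep pairs whose protein exceeds 25 residues and
   whose RNA has at least 15 nt (strict vs inclusive exactly as stated).
2. **Pair-level de-redundancy** — a greedy scan in input order discards
   a pair only when some already-retained pair is similar on *both*
   partners (protein identity ≥ 30% *and* RNA identity ≥ 30%). Identical
   proteins binding unrelated RNAs are genuinely distinct observations
   and are all kept. Greedy keep-first makes the operation deterministic
   and idempotent.
3. **Negative sampling** — uniform random protein × RNA pairing under a
   seed, rejecting exact positives and any candidate (A, B) for which a
   positive (C, B) exists with identity(A, C) ≥ 30%: a random pairing
   that resembles a known interaction is not a trustworthy negative.
   Sampling is rejection-based with an attempt cap, and errors report
   the achievable count when the admissible pool runs dry.

Pairwise identity itself is not uniquely defined by "30% identity", so
the package fixes one scheme: global Needleman–Wunsch alignment with
match +1, mismatch 0, gap −1 per position (via Biostrings), identity =
identical aligned positions / alignment length. Because optimal
alignments can tie, the implementation canonically orders the two
sequences before aligning, making the function exactly symmetric. Any
reasonable scheme preserves the pipeline's semantics; determinism and
reproducibility were the deciding criteria.

## Evaluation

`cross_validate()` uses stratified folds under a seeded shuffle, scores
every pair exactly once while held out, and pools confusion counts over
folds (micro-averaging), since benchmark results are conventionally
reported as a single number per dataset. Undefined ratios (e.g.
precision with no positive calls) are `NA`, never silently 0. ROC
curves group tied scores into single threshold steps, so the
trapezoidal area equals the Mann–Whitney concordance probability with
ties counted ½ — the property the test suite verifies against a
brute-force concordant-pair oracle to 1e-12.

Folds are drawn over *pairs*, not over sequences. When the same protein
(or near-identical sequences) occurs in several pairs, train and test
folds share that protein, which biases cross-validated estimates
upward. De-redundancy at 30% limits but does not eliminate this; a
sequence-disjoint split would be stricter and is not implemented.

Network evaluation reports **recall only**: interaction databases list
experimentally supported positives and contain no validated
non-interacting pairs, so percentages of known pairs recovered must not
be read as accuracy. `recall_on_known()` also bands recovered pairs by
probability (≥ 0.80 vs 0.50–0.80), the standard way to separate
high-confidence predictions.

## The synthetic generator

`generate_synthetic()` emulates the one property the classifiers
exploit — compositional separability — and nothing else. Background
residues are i.i.d. uniform over the molecule's alphabet. In positive
pairs, scanning left to right, each sliding position is selected with
probability δ and a signal k-mer is written there: a residue triplet
freshly realized from the signal triad's classes (default "215", i.e.
{I,L,F,P}{A,G,V}{R,K}) on the protein side, a signal tetrad (default
AUUC) on the RNA side. A draw that would overlap an already-planted
k-mer is skipped, so every planted k-mer survives intact; overwriting
(rather than inserting) keeps lengths fixed so window counts never
shift between classes. At δ = 0 the class distributions are identical
by construction, giving a proper permutation null.

Defaults — protein length 150, RNA length 100, 200 pairs per class for
the learnability and null conditions — are typical scales for
structure-derived RPI data and small enough that the full test battery
(about 26 cross-validation runs) completes in minutes; the
monotonicity-in-δ property uses 100 pairs per class over
δ ∈ {0, 0.1, 0.3, 0.5} with 5 seeds each.

What passing these tests shows: the encoders, learners, calibration and
evaluation machinery correctly recover a known compositional signal and
stay at chance when none exists. What it does not show: performance on
real data, where composition signals are weaker, classes are defined by
an incomplete database, sequences are phylogenetically correlated, and
background composition is far from uniform (ribosomal sequence bias is
the dominant example). Published benchmark figures on structure-derived
datasets (ten-fold cross-validated accuracies in the 70–90% range, AUC
0.8–0.97, and organism-level network recall from ~47% to ~99%) depend
on those datasets' exact membership and are treated here as integration
benchmarks: they require the original PDB/NPInter-derived inputs, which
are not redistributed with the package.

## Numerical and design notes

- **Invalid letters** (ambiguity codes, X, protein U) are retained in
  sequences and flagged; any k-mer window containing one contributes to
  neither numerator nor denominator of the frequencies. Dropping whole
  sequences would be needlessly aggressive; imputing letters would
  fabricate signal. A sequence with *no* valid window is an error at
  encoding time and a skipped-with-warning record in network scoring.
- **Normalization denominator** is the number of valid windows (=
  L − k + 1 for clean sequences), keeping each part summing to 1 even
  with skipped windows.
- **Kernel form**: the polynomial kernel includes the +1 lower-order
  term before normalization, the common form in the kernel family the
  defaults were tuned on. Self-similarity is exactly 1; Gram matrices
  on non-negative features are PSD (verified spectrally in tests).
- **SVM margin orientation**: the underlying solver's decision-value
  sign convention proved dependent on internal label ordering, so the
  orientation is established empirically from training margins at fit
  time and stored with the model.
- **RF ties at 0.5** are resolved positive by the inclusive threshold;
  all per-tree randomness derives from the single model seed, so
  identical seeds give identical models.
- **Feature importance** (mean Gini impurity decrease) is meaningful
  only with enough trees: at 20 trees each of the 599 features is
  evaluated in a handful of splits and ranks are noise-dominated, so
  importance analyses use the 500-tree setting while prediction keeps
  the fast 20-tree forest.
- **Forward selection** evaluates candidate subsets by internal
  cross-validated accuracy of a restricted forest; zero-variance
  subsets are scored as the majority-class baseline (the forest grower
  cannot split on them). The search is plain greedy forward selection —
  simpler than best-first search with backtracking, but transparent and
  monotone in its training-score trace.
- **Supplementary pair-list dialects**: published pair files may carry
  raw sequences or identifiers; `read_pairs()` takes an explicit
  dialect flag (`seq_pairs` assigns deterministic row-numbered ids,
  `id_pairs` resolves against loaded FASTA and errors naming unresolved
  ids) rather than guessing.

## Known limitations

- Composition-only features cannot distinguish sequences with equal
  k-mer spectra, and carry no positional or structural information.
- Pair-level (not sequence-disjoint) cross-validation optimism, noted
  above.
- Negative training pairs are presumed, not validated, non-interactions.
- The identity scheme for the 30% thresholds is one reasonable choice
  among several; absolute pair counts after de-redundancy depend on it.
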