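---
title: "Methods: pseudouridine site prediction in pseuvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudouridine site prediction in pseuvote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pseudouridine (Ψ) is the isomerized form of uridine and the most abundant
post-transcriptional RNA modification; it affects RNA structure, stability
and translation. Experimental mapping of Ψ sites is laborious, so sequence-
based classifiers are used to prioritize candidate sites. The unit of
classification is a fixed-length, U-centered window of λ nucleotides (λ odd;
the benchmark collections in this field use 21 or 31 nt): the question is
whether the central U is pseudouridylated. Windows come as balanced positive
(site) and negative (non-site) sets; arbitrary-length RNA is handled by
sliding the fixed window over every eligible U (see *Scanning*).

# Feature descriptors

Six descriptors encode each window. They share one canonical ordering:
nucleotides A, U, C, G and the 16 dinucleotides in lexicographic order over
that alphabet (AA, AU, AC, AG, UA, ..., GG). For window length λ:

| descriptor | dimension | what it captures |
|---|---|---|
| one-hot | 20λ − 16 | raw sequence: 4 indicator bits per position + 16 per dinucleotide position |
| k-mer (k = 1, 2) | 20 | global mono- and dinucleotide frequencies |
| k-nucleotide density (KD) | 2λ − 1 | position-coupled running frequencies |
| PseDNC | 16 + λ_pse | composition plus sequence-order correlation |
| PSKP | 2λ − 1 | class-contrastive positional propensities |
| NCP | 3λ | per-residue chemical properties |

**k-nucleotide density.** The value at position *i* is the count of the
residue observed at *i* within the prefix 1..*i*, divided by *i* (and
analogously over dinucleotide positions). A printed form of this definition
that sums over the whole sequence would make the value independent of
position; we use the prefix form, which matches the k-density literature and
the descriptor's stated purpose of coupling position with frequency.

**PseDNC.** The 16 dinucleotide frequencies *f* are augmented with λ_pse
correlation factors θ_j, where θ_j is the mean, over all dinucleotide pairs
*j* positions apart, of the mean squared difference of three standardized
physicochemical properties (free energy, stacking energy, hydrophilicity).
The full vector (f / (1 + wΣθ), wθ / (1 + wΣθ)) is non-negative and sums
to 1. λ_pse (default 2) and the tier weight w (default 0.1, range (0, 1])
are exposed in `psednc_config()`; the defaults are the conventional
small-tier settings of the pseudo-composition literature. The property
table ships as a plain-text file
(`inst/extdata/rna_dinucleotide_properties.tsv`): the free-energy column is
the Turner nearest-neighbor ΔG°37 set; the stacking-energy and
hydrophilicity columns follow the compilations circulated in the RNA
pseudo-composition literature. Any user table with the same columns can be
substituted, and no result in the test suite depends on the numerical
values — all PseDNC assertions are structural (dimension, non-negativity,
sum-to-one, vanishing θ on homopolymers).

**PSKP.** For each position, the frequency of each (di)nucleotide among
positive windows minus its frequency among negatives; a window is encoded
by looking up its own residues in this table. The table is label-derived,
so it is refitted on the training portion of **every** cross-validation
fold — both in the outer evaluation harness (`kfold_cv`, `ensemble_cv`) and
inside the BPSO fitness CV (`run_bpso`'s `fold_data` argument) — never on
data the fold will score.

**NCP.** A → (1,1,1), U → (0,0,1), C → (0,1,0), G → (1,0,0): ring
structure, functional group, hydrogen-bond strength.

Input handling: FASTA records are uppercased, T is silently mapped to U
(DNA-alphabet copies of RNA data are common); ambiguity codes are rejected
rather than imputed because every descriptor above is defined only over the
four-letter alphabet.

# Joint feature and hyperparameter selection

Each descriptor's feature set is pruned by binary particle swarm
optimization over a hybrid bit-string: `n_features` mask bits followed by
10 bits that index the RBF-SVM hyperparameters on a geometric grid —
2⁻¹⁶ ≤ C, γ ≤ 2¹⁵ with common ratio 2, so 32 values per parameter and 1024
combinations, in bijection with the 10 bits (5 per parameter,
most-significant bit first, C before γ; the bit convention is arbitrary but
frozen). Fitness is the mean stratified 10-fold cross-validation accuracy
of the RBF-SVM on the masked columns with the decoded (C, γ). The fold
partition is fixed once per search so every particle is scored on the same
folds.

The search runs in two phases:

* **Phase 1** (iterations ≤ `phase_switch_iteration`): canonical
  sigmoid-transfer binary PSO. Velocities update as
  v′ = w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x), clamped to ±v_max
  (default 6); each position bit is then drawn 1 with probability
  1/(1 + e^(−v)).
* **Phase 2**: once the exploratory phase plateaus, each bit is replaced by
  the corresponding global-best bit with probability sigmoid(|v|) (≥ ½, near
  1 at saturated velocities) and kept otherwise, collapsing the swarm onto
  the incumbent while residual velocity still permits local moves. This rule
  is this package's own documented design (the `phase2_rule` hook accepts
  alternatives); it reproduces the qualitative behavior expected of a
  late-phase accelerator — rapid convergence and near-frozen particles —
  without claiming to be any particular published variant.

Defaults are the full-scale settings the predictor is designed around:
80 particles, 300 iterations, switch at 200, v_max = 6, 10 folds. The
inertia schedule (0.9 linearly down to 0.4) and c1 = c2 = 2 are the
standard PSO settings; the search is robust to them, and they are
config-exposed. An all-zero feature mask has undefined fitness and is
repaired by setting one uniformly random mask bit. The global best never
regresses, so the fitness history is non-decreasing by construction, and a
run is bit-reproducible from `random_seed`.

# Base predictors and fusion

One RBF-kernel SVM per descriptor is trained (via libsvm through e1071,
`scale = FALSE`) on the full training set's selected columns with the
decoded (C, γ). Signed margins are re-oriented so positive always means the
Ψ class, since libsvm orients them toward the first-seen training label.

The six base predictors are fused in parallel by majority vote on hard
labels: more than three votes win. Six voters can tie 3–3; the default tie
rule takes the sign of the summed signed margins and calls a zero sum
positive — it uses available evidence rather than a coin flip and is
deterministic. Margins influence nothing except ties. A serial-fusion
baseline (concatenate the six masked blocks, retrain a single grid-searched
SVM) is shipped for comparison only; heterogeneous per-descriptor decision
boundaries are the argument for voting over concatenation.

# Evaluation

Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy, and the
Matthews correlation coefficient
MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)); a zero factor in the
MCC denominator yields MCC = 0 (the standard convention for degenerate
tables). Cross-validation is stratified (fold sizes within one sample,
class ratio preserved within one sample) and metrics are pooled over the
concatenated out-of-fold predictions rather than averaged per fold — with
10 folds of ≈20 windows, per-fold metrics are noisy and pooling keeps the
numbers comparable across configurations. The incremental-feature-selection
baseline ranks features by a two-group F statistic (the criterion is
configurable; no single canonical choice exists) and scores nested top-k
subsets by the same CV with a grid-searched (C, γ). Base-predictor
diversity is summarized by the 6×6 Pearson correlation matrix of their
prediction vectors; weak correlation is what makes the vote effective.

# Synthetic data

The package is exercised end to end on synthetic fixtures, so no external
download is needed.

**Window fixtures** (`fixture_spec`, `generate_dataset`) emulate the
benchmark structure: balanced U-centered windows whose positive class
carries a position-specific composition bias — at each designated signal
position the designated nucleotide's probability is background + strength.
Defaults: 100 + 100 windows of 21 nt, four signal positions spread around
the center, strength 0.6 over a uniform background. The signal is a
composition bias, not a fixed motif, so the position-sensitive descriptors
(one-hot, NCP, PSKP) and the compositional ones (k-mer, KD, PseDNC) see
partially independent evidence, emulating the heterogeneity that makes the
ensemble work. What these fixtures do **not** model: real pseudouridylation
motifs, structure context, base composition skew, or class imbalance —
passing tests demonstrate the machinery is correct and the pipeline
recovers planted signal, not that any particular accuracy will transfer to
biological data.

**Feature-matrix fixtures** (`generate_feature_fixture`) plant
`n_informative` Gaussian columns with a class mean shift against pure-noise
columns, for selection experiments with column-level ground truth. The
defaults (100 samples, 10 informative / 90 noise, shift 0.8 SD) are chosen
so the experiment is informative: the informative-only mask cross-validates
clearly above the all-features mask, i.e. noise inclusion measurably
dilutes the RBF distances. With a much larger shift or sample size,
accuracy saturates for essentially any mask and a selection experiment
measures nothing.

**Long-RNA fixtures** (`generate_long_rna`) splice positive-class windows
into background sequence at known positions for scanner recovery checks.

# Scanning arbitrary-length RNA

Every U whose full λ-window fits inside the input yields one candidate
window, classified by the ensemble; U's within (λ−1)/2 of either end are
reported in a skipped-positions list rather than padded — the encoders are
undefined over non-ACGU symbols, and silent dropping would hide sites from
the user. Output positions are 1-based (the convention of site-annotation
tables); the optional BED export uses 0-based half-open coordinates, as BED
requires.

# Problem sizes and numerical choices in the shipped tests

The test suite runs the full pipeline at reduced scale, chosen so the whole
suite completes in minutes while every code path is exercised: unit tests
use 9–21 nt windows, swarms of 4–8 particles and 2–6 iterations; the
end-to-end experiments use the fixture defaults above with searches of
20 × 30 (selection recovery), 10 × 10 (ensemble gain) and 6 × 6
(scanner recovery) particles × iterations. At these search budgets the
swarm improves its fitness and recovers most planted features, but mask
density stays near one half — thorough pruning of a large noise majority
needs the full-scale budget (and is the main cost of the method; the
full-scale harness is `scripts/benchmark_fullscale.R` in the source
repository).

Other fixed numerical choices, for the record: ties in the vote resolved by
summed margins then positive; MCC 0 on degenerate tables; all-zero masks
repaired by one random bit; hyperparameter bits most-significant first,
C block before γ; fold partitions derived from the run seed; one master
seed derives all per-descriptor seeds in ensemble training.

# Known limitations

* The full-scale search (80 × 300 per descriptor, six descriptors) is
  computationally heavy by design; desk-scale runs demonstrate mechanism,
  not published-scale accuracy.
* At small search budgets BPSO prunes only partially (mask density ≈ ½), so
  selected subsets on heavily noise-dominated inputs retain noise columns.
* The PseDNC stacking-energy and hydrophilicity columns are literature
  compilations shipped for convenience; users wanting exact provenance
  should supply their own table via `psednc_config(properties = ...)`.
* Majority voting requires exactly six base predictors; there is no
  weighted or learned fusion.
* No probability calibration: margins order predictions but are not
  probabilities.
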