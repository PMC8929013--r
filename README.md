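# pseuvote

Pseudouridine (Ψ), the isomerized form of uridine, is the most abundant
post-transcriptional RNA modification and matters for RNA structure,
stability and translation. `pseuvote` is an R package for sequence-based
prediction of Ψ sites: it classifies fixed-length, U-centered RNA windows
(21 or 31 nt in the common benchmark collections) as site / non-site, and
localizes candidate sites in arbitrary-length RNA with a sliding window.
It is aimed at computational biologists who want a self-contained,
reproducible implementation of a descriptor-ensemble Ψ predictor — every
stage can be exercised on built-in synthetic fixtures with planted signal,
no external download required.

## The method

Each window of length λ is encoded by six complementary descriptors:
one-hot indicators of every nucleotide and dinucleotide position
(20λ − 16 dims), k-mer frequencies for k ∈ {1,2} (20 dims), k-nucleotide
prefix densities (2λ − 1), pseudo dinucleotide composition with
physicochemical correlation tiers (16 + λ_pse), position-specific
k-nucleotide propensities fitted as class frequency differences (2λ − 1),
and nucleotide chemical properties (3λ).

For each descriptor, a binary particle swarm optimizer searches a hybrid
bit-string — a feature mask plus 10 bits indexing the RBF-SVM
hyperparameters on the geometric grid 2⁻¹⁶ ≤ C, γ ≤ 2¹⁵ (ratio 2; 1024
combinations) — with fitness the stratified ten-fold cross-validation
accuracy. Velocities follow v′ = w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x)
clamped to ±6, with sigmoid-transfer bit sampling; a late phase accelerates
convergence by drawing bits onto the global best. The six tuned RBF-SVMs
are fused by majority vote (ties broken by summed signed margins), and
performance is reported as SN, SP, ACC and MCC.

## Worked example

Train a small ensemble on a synthetic fixture with planted composition
bias, cross-validate it, and scan a long RNA containing one planted site:

```r
library(pseuvote)

spec <- fixture_spec(n_pos = 40, n_neg = 40, window_length = 11,
                     signal_positions = c(2, 4, 8, 10),
                     signal_strength = 0.7, seed = 303)
fx <- generate_dataset(spec)

ens <- train_ensemble(fx$dataset,
                      bpso = bpso_config(n_particles = 5, n_iterations = 3,
                                         phase_switch_iteration = 2,
                                         cv_folds = 5, random_seed = 11),
                      seed = 11)
ens
#> ensemble_predictor: 6 base predictors, window 11 nt, tie rule 'margin'
#>   ONEHOT   100/ 204 features, C = 2^5, gamma = 2^-2
#>   KMER      11/  20 features, C = 2^7, gamma = 2^14
#>   KD        12/  21 features, C = 2^4, gamma = 2^-2
#>   PSEDNC    11/  18 features, C = 2^13, gamma = 2^4
#>   PSKP       8/  21 features, C = 2^-14, gamma = 2^3
#>   NCP       17/  33 features, C = 2^12, gamma = 2^-3

cv <- ensemble_cv(fx$dataset, ens$selections, k = 5, seed = 1)
round(unlist(cv$ensemble), 3)
#>    SN    SP   ACC   MCC
#> 0.875 0.875 0.875 0.750

long <- generate_long_rna(60, data.frame(position = 20,
                                         window = unname(fx$dataset$sequences[1])),
                          seed = 4)
scan <- scan_sequence(long$sequence, ens, seq_id = "example_rna")
scan
#> site_scan: 8 candidate windows (1 called positive), 3 skipped U
head(scan$calls[, c("seq_id", "position", "label")])
#>        seq_id position label
#> 1 example_rna       10     0
#> 2 example_rna       13     0
#> 3 example_rna       25     1
#> 4 example_rna       32     0
#> 5 example_rna       40     0
#> 6 example_rna       42     0
```

Each `ensemble_predictor` line shows the selected subset size and the
decoded (C, γ) per descriptor; the cross-validation line gives pooled
out-of-fold sensitivity, specificity, accuracy and Matthews correlation;
the scan reports one row per U whose full window fits in the input
(1-based center position), with U's too close to either end listed as
skipped. Here the one planted site (window spliced at position 20, so its
center U is at position 25) is the single positive call.

The search settings above are demonstration-scale; the defaults of
`bpso_config()` are the full-scale settings (80 particles, 300 iterations,
phase switch at 200), which is what published-scale accuracy requires —
see `vignette("pseuvote-methods")` for the model, its assumptions, and
what desk-scale runs do and do not show.

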