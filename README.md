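# dhtppi

Sequence-based prediction of protein–protein interactions (PPIs) in
plants. Experimental PPI mapping (yeast two-hybrid, AP-MS) is slow and
expensive, so genome-scale interactome work leans on classifiers that
predict whether two proteins interact from their amino-acid sequences
alone. `dhtppi` implements one such pipeline end to end, for
bioinformaticians who want to train, evaluate, and benchmark it on their
own interaction datasets — plus a fully synthetic data generator so the
whole pipeline can be exercised and validated without any external
database.

## Method

For each protein with sequence length *U*:

1. **Evolutionary profile.** PSI-BLAST (3 iterations, inclusion E-value
   0.001, against a user-supplied database such as SwissProt) produces a
   position-specific scoring matrix (PSSM): a *U* × 20 matrix
   *Q* = {η<sub>a,b</sub>} of per-position log-odds substitution scores.
   A BLOSUM62 substitution profile (SMR) is available as an
   alignment-free comparator.
2. **Condensation.** The variable-length profile is condensed to a fixed
   20 × 20 matrix *M* = *Q*ᵀ*Q* / *U* (length-normalised amino-acid
   co-substitution; a pad/truncate mode is also provided).
3. **Local energy via the 2-D discrete Hilbert transform.** The 2-D
   discrete analytic signal of *M* is computed in the frequency domain:
   *X* = IDFT[ DFT(*M*) · (h ⊗ h) ], where h(0) = 1, h(k) = 2 for
   0 < k < n/2, h(n/2) = 1, h(k) = 0 otherwise. The element-wise modulus
   |*X*| ("local energy"), flattened, is the 400-dimensional descriptor.
4. **SVD reduction.** Descriptors are centred and projected onto the top
   300 right singular directions (Eckart–Young-optimal noise reduction),
   fitted on the training fold only.
5. **Pair classification.** A pair (A, B) is the 600-d concatenation of
   the two reduced descriptors, scored by a small feedforward network —
   two ReLU hidden layers of 48 neurons, sigmoid output, binary
   cross-entropy loss, Adam optimiser, dropout 0.5 — in a merged or
   Siamese-fusion architecture. KNN (k = 5) and random-forest (500
   trees) baselines share the same scoring contract.
6. **Evaluation.** Five-fold cross-validation reporting Acc, PR
   (precision), Sens, Spec, MCC and ROC/AUC, with negatives drawn
   uniformly from the complement of the known interactions in the
   all-pairs bipartite candidate space.

## Worked example

Generate a synthetic dataset (60 proteins, 300 balanced pairs, planted
interaction signal) and cross-validate the full pipeline:

```r
library(dhtppi)
ds <- gen_dataset(synth_config())          # seed-pinned, reproducible
report <- run_cv(ds$records, ds$pairs, ds$profiles)
print(report)
```

```
Testing set  Acc (%)         PR (%)          Sens (%)        Spec (%)        MCC (%)         AUC
1            90.00           90.00           90.00           90.00           80.00           0.9522
2            91.67           93.10           90.00           93.33           83.38           0.9633
3            91.67           93.10           90.00           93.33           83.38           0.9889
4            93.33           90.62           96.67           90.00           86.86           0.9578
5            86.67           86.67           86.67           86.67           73.33           0.9422
Average      90.67 +/- 2.53  90.70 +/- 2.66  90.67 +/- 3.65  90.67 +/- 2.79  81.39 +/- 5.12  0.9609 +/- 0.0175
```

Each row is one held-out fold; the average row shows the fold mean ±
sample SD. The mean AUC of 0.96 says the pipeline recovers the planted
interaction structure almost perfectly; MCC (here on a 0–100 scale)
summarises the balanced agreement at the 0.5 decision threshold.
Shuffling the labels drops the AUC to ≈ 0.5, confirming the signal is
real rather than an artefact of the harness.

Real data enter through `read_fasta()`, `read_pair_list()` and
`parse_ascii_pssm()` (the `psiblast -out_ascii_pssm` format), or
`run_psiblast()` to invoke PSI-BLAST directly. A thin CLI
(`exec/dhtppi`) exposes `simulate`, `features`, `evaluate` and `compare`
subcommands over the same functions.

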