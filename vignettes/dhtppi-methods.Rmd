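---
title: "Predicting plant protein-protein interactions from evolutionary profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dhtppi methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhtppi)
```

## The model

`dhtppi` predicts whether two proteins interact from sequence-derived
evolutionary profiles. The chain is:

profile (U x 20) -> condensed matrix (20 x 20) -> 2-D analytic-signal
local energy (400-d) -> SVD projection (300-d) -> pair concatenation
(600-d) -> feedforward classifier -> five-fold cross-validated metrics.

The underlying assumption is the standard one for profile-based PPI
prediction: interacting proteins carry correlated evolutionary
signatures, and those signatures survive (i) condensation of the
variable-length PSSM into a fixed-size amino-acid co-substitution
matrix and (ii) a spectral "local energy" summary of that matrix. The
classifier then learns which joint signatures co-occur in interacting
pairs. Nothing in the pipeline uses structure, localisation or
annotation — sequence is the only input.

### The discrete Hilbert transform step

The feature extractor is the 2-D discrete analytic signal. For a real
vector of length n, the analytic signal is computed in the frequency
domain: take the DFT, multiply bin k by h(k) with h(0) = 1, h(k) = 2
for 0 < k < n/2, h(n/2) = 1 (even n), h(k) = 0 above n/2, and invert.
Its defining properties — the real part equals the input, and the
spectrum is one-sided — are asserted directly in the test suite at
1e-9. For the 20 x 20 condensed matrix we use the separable
single-orthant construction: the 2-D DFT is multiplied by the tensor
product h &otimes; h. Because the mask is separable, this is exactly
the result of applying the 1-D transform along every column and then
every row; that equivalence (to 1e-10 over random matrices) is the
oracle we verify the 2-D code against. The feature value is the
element-wise modulus of the complex analytic matrix — the local energy
— flattened row-major to 400 numbers.

Two readings of "local energy" are defensible (modulus or squared
modulus); the package defaults to the modulus and exposes
`features.energy = "squared"`. Similarly, stacking the real and
imaginary parts instead of taking the modulus would double the
dimension to 800; we keep the energy reading, which preserves the
400 -> 300 -> 600 dimension chain.

### Condensation

How a U x 20 profile becomes 20 x 20 is genuinely open. The default is
the normalised cross-product M = t(P) %*% P / U: it is
length-invariant in scale, symmetric positive semi-definite, invariant
to reordering of sequence positions, and it is the standard
PSSM-to-400-feature construction in this literature. The alternative
`padtrunc` mode (keep the first 20 rows, zero-padded) matches the
pad/truncate convention of classical 2-D transform routines and is
selectable via `condense.mode`; it retains position order but discards
everything beyond residue 20, so we do not recommend it for real
proteins.

Profile entries are raw integer log-odds by default. `profile.normalize
= TRUE` applies a per-entry logistic map 1/(1 + exp(-x)); both
conventions appear in the PSSM-features literature and the choice is
exposed rather than hidden.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `psiblast.iterations` | 3 | iterations | standard profile-search depth for PSSM construction |
| `psiblast.evalue` | 0.001 | E-value | profile inclusion threshold (`-inclusion_ethresh`); applying it to inclusion rather than reporting is the reading that affects the PSSM |
| `condense.mode` | crossproduct | — | see above |
| `features.kind` | dht | dht/dct/fft/dwt/ac | DHT is the method; others are comparators |
| `features.ac_lag` | 5 | lags | auto-covariance comparator dimension 20 x g = 100 |
| `svd.k` | 300 | dimensions | the 400 -> 300 noise-reduction step |
| `svd.paper_mode` | FALSE | — | fit the projector on all data (legacy protocol) instead of the training fold |
| `pair.symmetrize` | TRUE | — | interaction is symmetric; train on both orientations |
| `dnn.hidden` | 48, 48 | neurons | two hidden layers of 48 |
| `dnn.dropout` | 0.5 | rate | standard inverted-dropout rate for small dense nets |
| `dnn.learning_rate` | 0.001 | — | Adam's conventional step size |
| `dnn.epochs` / `dnn.batch_size` | 100 / 64 | — | converges on the study-size datasets well inside a minute |
| `baseline.knn_k` / `baseline.rf_trees` | 5 / 500 | — | conventional baseline settings |
| `cv.k` | 5 | folds | five-fold cross-validation |
| `threshold` | 0.5 | score | hard-label decision point; ties count as positive |

The network's unstated details are fixed, documented choices:
Glorot-uniform initialisation, Adam with beta1 = 0.9, beta2 = 0.999,
eps = 1e-8, inverted dropout on hidden activations during training
only, and a decision threshold of 0.5. Every random draw
(initialisation, shuffling, dropout) derives from `dnn.seed` /
`cv.seed`, so a configuration plus seeds determines the whole run
byte-for-byte; the test suite checks this end to end by comparing
written reports from two identical runs.

### Merged vs Siamese architectures

Two architectures are implemented because the method admits two
readings: a single merged network fed the 600-d pair descriptor (the
reading that matches "two hidden layers of 48"), and a Siamese-fusion
network in which each 300-d half passes through its own twin layer
before the twin outputs are concatenated and fused. The merged form is
the default. The Siamese form gives the twins independent weights
(they are twins in topology, not in parameters); it is implemented as
a single network whose first layer carries a block-diagonal
connectivity mask applied to both the initial weights and every
gradient update — algebraically identical to two separate subnetworks,
and asserted structurally in the tests (off-block weights stay exactly
zero through training; free-parameter counts match 2 x twin + fusion).

### Leakage policy for the SVD

Fitting the projector on all descriptors before splitting folds leaks
test-set information into the representation. The default therefore
fits the SVD on the training fold's proteins only and applies it to
the held-out fold. `svd.paper_mode = TRUE` restores the global fit for
users who want to mirror the older protocol; on the synthetic data the
difference is small, but the honest default is fold-wise.

## The synthetic data generator

The generator stands in for curated plant interaction datasets, which
cannot be bundled. It emulates, mechanistically, the assumption the
pipeline exploits — interacting proteins share profile structure:

- Each protein gets a latent 20-vector: a common non-negative direction,
  jittered per protein, scaled by an interaction propensity m ~ U(0.2,
  1.8). Ground-truth interaction is a latent dot product above 0.8.
- Profiles are integer log-odds: Gaussian noise (sd 2, clamped to
  [-10, 12], the magnitude range of real PSSM scores) plus the planted
  rank-1 term 3 x `signal_strength` x latent added to every position
  row, so the condensed cross-product matrix carries the latent outer
  product above the noise floor.
- Positives are sampled among interacting pairs; negatives are drawn
  uniformly from the bipartite complement, excluding an ambiguous
  margin band (dot product in (0.6, 0.8]) — the analogue of benchmark
  construction, where sampled negatives are kept away from known
  positives. Sampled positive pairs are stored in random slot order so
  that listing order carries no label information.
- At `signal_strength = 0` the labels are decoupled from the latents
  entirely: pairs are drawn uniformly at random. This is deliberate.
  Even with pure-noise profiles, each protein's fixed profile is a
  fingerprint that identifies it across folds, so latent-derived labels
  would remain partly predictable through protein-identity
  memorisation (see Limitations); a true null requires labels
  independent of protein identity, not merely of profile content.

Defaults (60 proteins, lengths 50–200, 150 + 150 pairs, strength 2,
seed 7) are the study conditions used throughout the tests: large
enough that five folds of 60 pairs give stable metrics, small enough
that a full cross-validated run takes seconds. The acceptance script
uses the same sizes, plus a 320-protein set where the full
k = 300 projection is exercised.

What the generator does **not** emulate: real amino-acid composition
biases, homology between proteins (every sequence is i.i.d. random),
the heavy-tailed degree distribution of real interactomes, PSI-BLAST's
position-dependent profile structure (planted structure is uniform
across positions), and negative sets contaminated with undiscovered
positives. Passing the planted-signal tests therefore demonstrates
that the pipeline's machinery — features, reduction, classifier,
harness — can recover a profile-borne interaction signal; it does not
certify accuracy on any real interactome.

## Numerical choices and degenerate inputs

- Metric edge cases: any 0/0 ratio (e.g. precision with no predicted
  positives) is reported as 0 with a warning; a zero MCC denominator
  yields MCC = 0. Scores exactly at the threshold predict positive.
- ROC is built by sweeping the distinct scores as thresholds; the
  trapezoidal area then equals the tie-aware rank statistic, which the
  tests verify exactly, alongside an independent cross-check against
  pROC.
- Mean +/- SD rows use the sample SD (n - 1 denominator).
- SVD bases are sign-canonicalised (largest-magnitude entry of each
  column made positive) so fits are reproducible across linear-algebra
  backends; `k` is capped at min(n, p) with a warning.
- Stratified folds keep per-fold class counts within one sample of
  balance; fold sizes differ by at most one per class.
- The negative sampler enumerates the candidate space when it is small
  and falls back to rejection sampling above 2 x 10^6 candidates, so
  genome-scale protein sets do not materialise p^2 pairs in memory.
- Cross-entropy probabilities are clamped to [1e-12, 1 - 1e-12] inside
  the loss only, never in reported scores.
- PSI-BLAST runs that produce no PSSM (no hits) fall back to the
  BLOSUM62 substitution profile with a warning rather than aborting a
  batch; ambiguity codes B/Z/X/U map to all-zero substitution rows.

## Known limitations

- **Pair-level cross-validation leaks protein identity.** Folds
  partition *pairs*, not proteins, so a protein seen in training pairs
  reappears in test pairs. With any per-protein label propensity the
  classifier can exploit memorised protein fingerprints; this inflates
  pair-CV estimates relative to protein-disjoint splits. This is a
  property of the evaluation protocol itself; the synthetic null
  condition is designed around it (above), and users validating on real
  data should consider protein-disjoint splits as a complement.
- AUC on small test folds (60 pairs) is quantised; fold SDs of a few
  points are expected noise, which is why the monotonicity check on
  signal strength carries a one-SD tolerance.
- The DWT comparator is fixed to a single-level Haar decomposition
  (exactly rational, dimension-preserving: 4 x 10 x 10 = 400); other
  wavelet families would need a boundary-handling convention.
- The KNN baseline stores its training matrix; for genome-scale runs
  the RF or DNN classifiers are the practical choices.
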