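---
title: "Anticancer peptide classification with feature-space augmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticancer peptide classification with feature-space augmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpaug)
```

## The problem

Anticancer peptides (ACPs) are short (roughly 10–50 residue) peptides that
disrupt cancer-cell membranes selectively; experimentally screening candidate
sequences is slow, so sequence-based classifiers are used to triage them.
The benchmark setting this package targets is binary: experimentally
verified ACPs versus antimicrobial peptides without anticancer activity.
Benchmark sets in this area are small — a few hundred peptides — which is
the regime where classifiers are starved for training data. The package's
central idea is to enlarge training folds *in feature space*, by
noise-adding oversampling, rather than collecting or mutating sequences.

## Pipeline

Every evaluation run performs, in order:

1. **Length normalization.** Each peptide is brought to exactly `l_x`
   residues (`normalize_length()`): C-terminal padding with the letter `X`,
   or truncation that keeps the N-terminus. `X` is a first-class alphabet
   member mapping to all-zero features in every encoder. Truncation keeps
   the N-terminus because the positional features below are N-anchored.
   `l_x` is 40 by default and swept over {40, 50, 60} by
   `parameter_sweep()`; most benchmark peptides are shorter than 60
   residues, which is also the range the synthetic generator uses.

2. **Encoding** (`encode_dataset()`), concatenating up to three blocks in
   fixed order:
   * *Binary profile features (bpf)*: one-hot encoding of the first
     `k = 7` N-terminal residues over the alphabetically ordered 20-letter
     alphabet — 140 binary features.
   * *AAindex (aaindex)*: for each position, the values of all 531
     gap-free AAindex-1 physicochemical indices for that residue
     (position-major), giving `531 * l_x` features (21,240 at
     `l_x = 40`). The table is built at run time from the AAindex data in
     the seqinr package; any gap-free index-by-residue matrix can be
     substituted.
   * *k-mer (kmer)*: residues are mapped to 7 physicochemical classes,
     each peptide becomes a `7^K x (L - K + 1)` sparse 0/1 occurrence
     matrix (`K = 3`), and the matrix is compressed to a 343-vector.

3. **Feature selection** (`fit_mrmr()` / `apply_selection()`): the AAindex
   block is reduced to its `m = 50` most informative columns by greedy
   minimum-redundancy maximum-relevance selection, giving the default
   140 + 50 = 190-dimensional representation.

4. **Augmentation** (`augment_training_set()`): training folds are
   enlarged classwise by the masked multiplicative perturbation described
   below.

5. **Classification and scoring** (`run_cv()`): stratified five-fold
   cross-validation, a classifier per fold, and accuracy, precision,
   sensitivity, specificity and the Matthews correlation coefficient
   (MCC), all in percent, averaged over folds without weighting.

## The augmentation model

A pseudosample is generated from a uniformly drawn (with replacement)
training row `F_i` of one class as

```
F_new = F_i (1 + a V)     (elementwise)
```

where `V` is redrawn for every pseudosample, zero over the binary-profile
block and i.i.d. uniform on `[0, 1)` over the AAindex block, and
`a = 0.005`. Three consequences define the contract the tests assert:

* binary-profile columns of a pseudosample are bit-identical copies of the
  source row (a perturbation of a 0/1 code is meaningless);
* every AAindex entry moves away from zero by a relative amount in
  `[0, a)`; the expected relative perturbation is `a / 2`;
* `a = 0` reproduces sources exactly, making the no-op case testable.

The multiplicative (Hadamard) reading of the perturbation is the only one
under which a zero-masked `V` leaves the binary block unchanged, which is
the stated purpose of the mask. `V` is redrawn per pseudosample — the
variance-maximizing reading, and what noise-adding oversampling schemes
do in practice. Positives and negatives are augmented independently with
the same fraction, preserving the class ratio; the pseudosample count per
class is `round(n_fraction * class size)` with half-up rounding. The
fraction is swept over 100–300% by `parameter_sweep()`. The perturbation
coefficient defaults to `a = 0.005` for any dataset; it is a config knob
(`augmentation_config()`).

Augmentation happens strictly inside training folds, after feature
selection — the perturbation operates on the selected 190-dimensional
representation. Pseudosamples carry a provenance link to their source
row, and `run_cv()` asserts on every fold that no test-fold sample id
ever appears among augmentation sources (a leakage guard that fails the
run loudly rather than silently contaminating the evaluation).

## mRMR estimator choices

The literature names mRMR but rarely the estimator; these are the choices
made here, all deterministic:

* Features are discretized into three bins at `mu - sigma` and
  `mu + sigma` (a standard mRMR discretization); labels are binary
  already. Constant features land in the middle bin and carry zero
  mutual information.
* Mutual information is the plug-in estimate from the empirical joint
  distribution, in nats.
* The greedy criterion is the MID (difference) scheme: relevance minus
  mean redundancy against the already-selected set. The quotient scheme
  (MIQ) is available via `scheme = "MIQ"`.
* Ties break toward the lowest feature index, with a 1e-9 tolerance so
  that mathematically equal scores computed through different float paths
  still break identically.
* Selection is fitted inside each training fold, never on pooled data —
  the leakage-safe protocol. A `leaky_selection = TRUE` flag exists for
  reproducing published protocols that selected features once globally;
  its use is echoed in the report config.

The implementation computes all mutual-information terms for a greedy step
with three `crossprod()` calls on per-bin indicator matrices, which keeps
selection over the 21,240-column AAindex block to a few seconds per fold.
The test suite checks it against an independently coded exhaustive greedy
oracle on small fixtures, where the naive loop is feasible.

## k-mer reduction conventions

Two details of the k-mer block are underdetermined in the surrounding
literature and fixed here explicitly:

* The 7-class reduced alphabet defaults to {A,G,V}, {I,L,F,P}, {Y,M,T,S},
  {H,N,Q,W}, {R,K}, {D,E}, {C} — a standard physicochemical grouping.
  Any disjoint 7-group cover can be supplied via `kmer_config()`.
* The SVD reduction returns `sigma_1 * u_1` (leading left singular vector
  scaled by the leading singular value), with the sign fixed so the
  entry of largest magnitude is positive. The reduction is unique only
  when the leading singular value is simple; the oracle test therefore
  restricts itself to fixtures with a singular-value gap.
* Windows containing `X` produce all-zero columns rather than a pseudo
  class: padding must not create spurious k-mers.

## Classifiers

The reference classifier is a multilayer perceptron with six hidden
layers of 100 rectified-linear units and L2 penalty 0.01. No installed R
package provides a multi-hidden-layer perceptron, so the package
implements one (`mlp_fit()`): mini-batch Adam (learning rate 1e-3, batch
`min(200, n)`, up to 200 epochs with an early stop when the loss
stagnates for 10 epochs at tolerance 1e-4), numerically stable log-loss
computed from logits, Glorot-uniform initialization, zero biases, and a
fixed seed per fit. On the feature widths involved (a few hundred), dense
BLAS products make this fast; a fit on a few hundred samples takes
seconds. The test suite verifies it learns XOR (ruling out a silently
linear model), is bit-reproducible under a fixed seed, and decreases its
regularized loss.

The comparison families run through their established implementations —
`e1071::svm`, `randomForest`, `rpart`, and `ranger` with
`splitrule = "extratrees"` — at those packages' defaults, echoed into
every report.

Two scoring conventions: the classification threshold is 0.5 on the
positive-class score, never tuned; and the MCC numerator is the standard
`TP*TN - FP*FN` (one published statement of the formula contains an
obvious transcription slip in the numerator while printing the standard
denominator; the standard form is implemented). Metrics with zero
denominators are reported as `NA` (undefined), not zero, and excluded
from fold means.

## Feature scaling

By default `run_cv()` standardizes features per fold: the scaler (mean
and standard deviation per column) is fitted on the augmented training
rows and applied to both splits. This choice was made after observing
that raw AAindex columns span several orders of magnitude (chemical
shifts near 4, volumes above 100), which ill-conditions first-order
neural-network training badly enough that the MLP cannot separate even a
fully separable synthetic benchmark (fold MCC in the 70s rather than
>90). Standardization happens *after* augmentation, so the perturbation
contract above holds in raw feature space, and the raw-feature behavior
remains available via `standardize = FALSE`. The setting is recorded in
every report.

## The synthetic test bench

`generate_dataset()` emulates a labeled benchmark with a tunable
N-terminal compositional signal: negatives are i.i.d. uniform over the 20
residues; positives draw each of their first seven residues, with
probability `signal_strength`, from a distribution placing 90% of its
mass uniformly on {K, R, L, F, A} (cationic/hydrophobic, the composition
that makes membrane-active peptides recognizable) and 10% on the rest.
Lengths are uniform on 10–60 residues. The signal sits at the N-terminus
deliberately, so both the positional one-hot block and the AAindex block
can see it — exercising the rationale for concatenating them.

What the generator does *not* emulate: residue autocorrelation,
amphipathic periodicity, shared evolutionary ancestry between splits, or
class imbalance. Passing the synthetic acceptance checks therefore
demonstrates that the pipeline's machinery is correct and leak-free, not
that its accuracy on real benchmark data will reach any particular
value.

`generate_feature_fixture()` skips the sequence layer entirely and emits
class-shifted Gaussian feature matrices (signal columns shifted by
`effect_size` in the positive class), used by the selection and
augmentation tests.

Problem sizes for the standing evaluations were chosen once: 200 + 200
peptides for the strong-signal check (where the pipeline's mean
five-fold MCC exceeds 90), and ten seeds of 60 + 60 for the
null-signal check (50 fold-level MCCs, enough to pin the null mean
within a few points of zero), with 100 + 100 at `signal_strength = 0.45`
for the paired augmented-versus-plain comparison.

## Benchmark data

The public ACP740 (376 ACPs / 364 non-ACPs) and ACP240 (129 / 111)
benchmark FASTA files are third-party data and are not redistributed with
the package. `load_labeled_dataset()` reads them directly once placed
under `inst/extdata/benchmarks/` (see the README); the corresponding
acceptance test asserts the published class counts and that the
cross-validated MCC at the published best settings (`l_x = 40` with
100% augmentation for ACP740, 300% for ACP240) lands within five MCC
points of the published values. Without the files that test fails, by
design — it is not silently skipped.

## Known limitations

* The MLP is a faithful but independent implementation; its optimizer
  trajectory will not bit-match any other library's, so published table
  values can only be reproduced within cross-validation and seed noise.
* mRMR selection on the full AAindex block is refitted per fold;
  protocols that selected once globally will select slightly different
  features (the `leaky_selection` flag reproduces that reading).
* The three-bin discretization is a pragmatic standard, not an optimized
  estimator; with very small folds the middle bin dominates.
* `parameter_sweep()` re-encodes the dataset per grid cell; at benchmark
  scale this is minutes, not hours, and keeps the implementation simple.
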