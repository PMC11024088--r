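---
title: "Methods: entropy-based feature selection, property fingerprints and BBB classifiers"
author: "bbbfp developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based feature selection, property fingerprints and BBB classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbfp)
```

# The modelling problem

Whether a molecule passes the blood–brain barrier is, for modelling
purposes, a binary property derived from the steady-state
brain-to-blood concentration ratio: a compound with
$\log BB \ge -1$ is treated as BBB-permeating (*active*), anything
below as non-permeating (*inactive*). The boundary is inclusive —
`load_compounds()` labels a compound with $\log BB = -1$ active —
and an explicit label column always wins over the derived one (with a
warning when they disagree), because curated labels typically encode
information beyond the raw ratio.

The pipeline goes: **standardize → descriptors → select → encode →
split → train → evaluate**, each stage a standalone function and CLI
subcommand, with every tunable surfaced and every random choice behind
one seed.

# Dataset standardization

`standardize_dataset()` removes, in order: unparseable structures;
multi-fragment inputs (salts and mixtures) and structures containing
atoms outside the organic subset (H, B, C, N, O, F, P, S, Cl, Br, I);
compounds heavier than 1000 Da (strictly greater, so 1000.0 Da
survives); all copies of canonical-structure duplicates whose labels
contradict each other; and finally the surplus copies of consistent
duplicates. Each removal is logged with its reason, so
$|input| = |output| + |log|$ always holds and the operation is
idempotent. Canonicalisation and molecular weight come from RDKit
through a subprocess adapter; the weight used is the average molecular
weight (`MolWt`), the conventional reading of a dalton cutoff in
curation pipelines — the monoisotopic alternative would move almost no
compound across a 1000 Da line.

Missing-value semantics matter downstream: in a 2D structure-based
descriptor a missing value means *the probed substructure is absent*;
in a 3D descriptor it means *the computation failed*, and such
compounds are dropped from 3D tables rather than imputed.

# MI-DSE: scoring a descriptor's class separation

For descriptor $D$ with values binned into $B$ equidistant bins over
the **combined** (both-class) min–max range,

$$\mathrm{MIDSE}(D) = H_{AB}(D) - \frac{H_A(D) + H_B(D)}{2},$$

where $H_A$ and $H_B$ are Shannon entropies (base 2) of the normalised
class histograms and $H_{AB}$ is the entropy of their per-bin
arithmetic mean. Three design points deserve emphasis:

* **Imbalance invariance.** The combined histogram is the *mean of the
  normalised class histograms*, not the pooled histogram. Replicating
  every sample of one class any number of times leaves the score
  unchanged — the property the score was designed for, and one we
  assert to $10^{-9}$ in the test suite.
* **Base-2 logarithms** put the score in $[0,1]$ with no extra
  normalisation: two classes concentrated in two different single bins
  give $H_A = H_B = 0$ and $H_{AB} = 1$ exactly.
* **Shared support.** Edges span the combined range because the score
  compares the two distributions on one support; per-class ranges would
  make the entropies incomparable.

**Bin count.** The histogram bin count is not dictated by the method;
we default to `n_bins = 10`, the order of magnitude used when the score
is visualised against real descriptor distributions, and keep one
global value so scores are comparable across descriptors. It is a
plain argument for sensitivity analysis.

**Numerical conventions.** Bin edges are computed literally as
$lo + k\,(hi-lo)/B$; a value equal to an edge belongs to the lower bin
(the same convention the fingerprint boundaries use), the minimum
belongs to bin 1, and a degenerate zero-width range collapses to a
single bin with zero entropy (score 0). Tiny negative scores from
floating-point cancellation are clamped to 0. Missing values are
excluded before binning; a descriptor with fewer than 5 non-missing
values in either class is skipped with a warning rather than scored on
noise.

# Selection: threshold, redundancy, cap

`select_features()` applies, in this order: score threshold
(MI-DSE ≥ 0.1), sort by descending score (ties broken by descriptor
name for determinism), greedy Pearson-correlation pruning (a candidate
is dropped when $|r| \ge 0.8$ against any already-retained descriptor,
on pairwise-complete observations), then the cap of 50. The ordering
is a genuine design choice — the source rules are stated without an
order — and this one maximises retained information: pruning before
capping means the cap is spent on mutually non-redundant descriptors.

Structural keys are selected separately: any 2D descriptor whose
class-wise missing-value frequencies differ by at least 0.2 becomes a
key. MIN members of MAX/MIN electrotopological-state pairs are removed
first (their absence patterns are identical by construction), and
sum-type E-state descriptors can never qualify because they encode
absence as 0, not as a missing value.

# The fingerprint codec

`fit_schema()` freezes, **from training data only**, per-descriptor
boundaries $bound_i = val_{min} + i \cdot val_{range}/n$ for
$i = 0..n-1$ ($n$ = 4 or 8 bits), or the training median for 1-bit
fields. `encode()` then writes one prefix bit per structural key
(1 = substructure present) followed by thermometer fields: bin $j$ sets
the first $j$ bits. The bin rule — value ≤ first boundary → bin 0;
value > last boundary → top bin; otherwise the unique
$bound_i < v \le bound_{i+1}$ → bin $i{+}1$ — reduces to
$j = \#\{i : bound_i < v\}$, which is total, deterministic, and
monotone in $v$ (the thermometer property we fuzz with 10,000 draws).

The source description of the boundary index range is internally
inconsistent ("$i$ from 0 to 3 or 0 to 7" alongside "fifth or ninth
bin"); we resolve it as $i = 0..n{-}1$, which is the only reading
giving $n$ boundaries, $n{+}1$ bins and popcounts $0..n$. Consequently
bin 0 captures only values at or below the training minimum — a test
value below the training range maps to an all-zero field, one above it
saturates the field, and boundaries are never refit from test data.

A missing continuous value at encode time produces an all-zero field
and a per-compound flag. Zero bits are the "no information" state of a
thermometer code; any other choice would invent a value. A constant
training descriptor (zero range) is flagged `degenerate`: all
boundaries equal the minimum and any larger value saturates.

Schemas serialise to JSON with 17 significant digits, which makes the
write → read → encode round trip bit-identical (15 digits — the
jsonlite default — demonstrably is not enough; boundary ties flip).

# Kennard–Stone splitting

The modified Kennard–Stone splitter seeds the training set with the
globally maximal-distance pair, then repeatedly admits the candidate
whose distance to its nearest training sample is maximal. Supported
metrics: Euclidean; Mahalanobis with the covariance estimated on the
full input matrix and inverted by SVD pseudo-inverse (singular
covariances are routine in fingerprint space) with an optional ridge
term; and 1 − Tanimoto for bit vectors, where two all-zero vectors are
defined as identical (distance 0). Ties at every step break to the
lowest row index, making the algorithm fully deterministic; a
completely degenerate input (all points identical) selects the lowest
indices and warns.

"Incorporating the activities" into the distance is implemented
minimally: the 0/1 class label is appended as one extra unscaled
coordinate before distance computation. How the original authors
weighted it is not described; one unscaled coordinate is the least
committal reading and is flagged as such. The default training
fraction is 0.8, matching the published 1474/1842 composition.

A consequence users should expect: Kennard–Stone test sets are
*interior* points of the chemical space, so external metrics tend to
look better than cross-validation on the same data. That is a property
of the design, not a bug.

# Learners, grids and the applicability domain

Random forest and SVM classifiers are delegated to scikit-learn
through a subprocess adapter (`inst/python/learners.py`) — the same
library the reference models used — with all statistics computed on
the R side from returned out-of-fold probabilities. The published
grids are reproduced in `default_grids()`: for the imbalanced dataset,
RF depth 200–900 × trees 100–1000 (steps of 100) × {gini, entropy},
SVM C 0.7–1.2 × γ 0.1–0.4 (steps of 0.1), polynomial degree 1–5; for
the balanced dataset the explicit RF grid
{100, 500, 1000, 1500, none} × {100, 500, 1000, 1500} ×
{sqrt, log2, none} × {gini, entropy, log_loss} and log-spaced SVM
ranges ($10^{-4}..10^{4}$ for C, $10^{-4}..10^{2}$ for γ, degree 1–6).
Class weights follow $n_{samples} / (n_{classes} \cdot count_c)$
exactly.

Cross-validation is stratified (the imbalanced dataset would otherwise
risk inactive-free folds) with one fold assignment shared across the
whole grid, fixed by the seed. The metric that picks the winner is not
specified by the source; we default to mean CV **accuracy** — the
common exhaustive-grid default — configurable to any metric in the
report (MCC and balanced accuracy being the sensible alternatives for
imbalanced data).

Predicted labels are derived from the positive-class probability at
0.5 (ties → active) rather than taken from the learner, which
guarantees the probability/label consistency invariant; Platt-scaled
SVMs can otherwise contradict their own decision function near the
boundary.

Every trained model stores the training-data mean and covariance
pseudo-inverse in fingerprint space; `predict()` attaches the
**Mahalanobis applicability-domain distance** of each query to the
training cloud. The reference set defaults to *all* training compounds,
with an `"active"`-only option mirroring the alternative reading of
the source's parenthetical. The distance is reported raw, not
thresholded: cutting it off is a policy decision for the user, made
against the distribution of training-set self-distances.

# Metrics

All confusion-matrix metrics are evaluated literally: sensitivity,
specificity, accuracy, balanced accuracy, precision, F1 (the harmonic
mean of precision and recall), MCC, and Cohen's κ with chance
agreement $P_e = [(TP{+}FN)(TP{+}FP) + (FP{+}TN)(FN{+}TN)]/n^2$. A
metric whose denominator vanishes (MCC with an empty margin,
sensitivity with no positives) is reported as **undefined with the
zero margin named**, never silently 0 — silently zeroed MCCs are a
well-known source of inflated comparisons. ROC-AUC is computed by the
probability-sorted threshold sweep with tied scores collapsed into
diagonal segments, which makes it exactly the rank statistic
$P(s_+ > s_-) + \frac{1}{2} P(s_+ = s_-)$; the suite verifies the
equivalence against a brute-force pairwise oracle.

The summary metrics quoted in different parts of the source disagree
slightly; the externally validated confusion counts (325/0/1/33) are
taken as authoritative because they exactly reproduce the quoted MCC
of 0.984, and our acceptance checks are pinned to those counts.

# The synthetic-data generator

`generate_synthetic()` produces the statistical world the pipeline
assumes, with a ground-truth manifest: informative descriptors (active
class shifted by `separation` standard deviations, default 3 — a
strong but not trivial signal, comparable to a top-ranked polar
surface area descriptor), pure-noise descriptors, correlated pairs
(population $r = 0.95$, one member redundant) to exercise the PCC
filter, and structural keys realised as class-dependent missing-value
rates (defaults 0.1 active / 0.6 inactive, comfortably past the 0.2
discrepancy cut). An optional bimodal inactive class mimics the wider,
multi-modal spread real inactive compounds show. Presets mirror the
two modelled compositions: "imbalanced" (≈3.6:1 active majority) and
"balanced" (1:1).

What the generator does **not** emulate: real descriptor
distributions are skewed, heavy-tailed and discretised; descriptor
blocks are correlated in groups rather than pairs; and missingness
co-occurs across related descriptors. A green end-to-end test
therefore establishes that the machinery recovers planted structure
under clean conditions — it does not certify performance on any real
chemical dataset.

# Reproducibility

One global seed fans out to per-stage seeds through a deterministic
integer mix, so stages are independently reproducible; the resolved
configuration, every intermediate artifact, and a log are written to
the run directory, and re-running a configuration reproduces
fingerprints, splits and predictions exactly (learner seeds are pinned
through to scikit-learn). Compound and descriptor CSVs are written
with round-trippable precision (17 significant digits) because split
decisions and bin assignments can legitimately hinge on the last bits
of a double.

# Known limitations

* 3D descriptor computation is out of scope; 3D tables must be
  supplied precomputed, and all-missing 3D rows are dropped as failed.
* The learner layer requires a python with scikit-learn on PATH;
  determinism holds for fixed library versions but trained artifacts
  (joblib files) are not portable across scikit-learn major versions.
* The applicability-domain distance uses a single global Gaussian
  summary of the training cloud; strongly multi-modal training sets
  would deserve a per-cluster or nearest-neighbour AD measure.
* MI-DSE scores depend mildly on the bin count; rankings are stable in
  our tests but the absolute 0.1 threshold is calibrated for ~10 bins.
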