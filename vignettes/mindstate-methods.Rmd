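---
title: "Classifying driver mental states from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver mental states from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindstate)
```

## The problem

Long monotonous driving degrades vigilance, and EEG is the most direct
physiological window on that process. This package classifies short EEG
epochs into three mental states — drowsy (`DROWS`, label 0), maximally
awake (`TAV3`, label 1) and an intermediate neutral state (`TAVX`, label
2) — from a 15-channel scalp montage (Fz, Pz, Oz, Fp1, Fp2, F7, F3, F4,
F8, C3, C4, P7, P3, P4, P8) sampled at 256 Hz. The recordings such studies
produce are typically access-restricted, so the package ships a synthetic
generator that reproduces the statistical structure the method exploits;
everything downstream is agnostic about where the epochs came from.

The pipeline is: band-pass filter (1–40 Hz), cut 0.5 s epochs (15 × 128
matrices), extract spatial-variance features with a triclass common
spatial pattern (CSP) projection, and classify with a gradient-boosted
decision-tree ensemble that uses histogram-based split finding and
depth-limited leafwise growth.

## Spatial covariance and CSP

Each epoch is a channel-by-sample matrix $W \in \mathbb{R}^{X \times S}$
($X = 15$ channels, $S = 128$ samples). Its trace-normalized spatial
covariance is

$$C = \frac{WW^\top}{\operatorname{trace}(WW^\top)},$$

a unit-trace symmetric PSD matrix. Trace normalization removes global
amplitude, so the features are invariant to per-epoch gain — important
because electrode impedance drifts. Channels are mean-centered within the
epoch first; band-pass filtering already removes DC over long stretches,
centering closes the gap inside a short window and makes $C$ a covariance
proper.

For two classes with mean covariances $C_d$ and $C_t$, CSP whitens the
composite $C_c = C_d + C_t = E_c \lambda_c E_c^\top$ with

$$P = \lambda_c^{-1/2} E_c^\top, \qquad P C_c P^\top = I$$

(the inverse *square root* is what makes the whitening identity hold),
then diagonalizes the whitened target covariance
$S_d = P C_d P^\top = B \lambda_d B^\top$. Because $S_d + S_t = I$, the
same basis diagonalizes $S_t$ with eigenvalues $1 - \lambda_d$: the
component most expressive of one class is least expressive of the other.
The spatial filters are the rows of $B^\top P$, ordered by descending
$\lambda_d$.

Two conventions make this construction deterministic and summable:

* **Ordering** — filters are sorted by descending target-class eigenvalue.
* **Sign** — each filter row is scaled so its largest-magnitude
  coefficient is positive. Eigenvectors are sign-ambiguous, and without a
  fixed sign the sum of two projections (below) would depend on the
  eigensolver.

### The triclass extension

The awake state separates easily, so only the two harder states get their
own projection: a one-vs-rest binary CSP for the drowsy class ($P_A$) and
one for the neutral class ($P_B$), summed element-wise into the final
projection

$$P_N = P_A + P_B.$$

We considered contrasting each target class against the awake class only
rather than against the rest; one-vs-rest is the default because it uses
every training epoch in both binary problems and degrades more gracefully
when one class is undersampled (the alternative is available via
`contrast = "awake"`). All $X$ components are retained by default —
features are then 15-dimensional — with `n_pairs` available to keep only
the extreme filters of each binary problem.

An epoch's feature vector is the per-row variance of $F = P_N W$, the
*plain* variance rather than the conventional log-variance: the
tree-based classifier downstream is invariant to monotone transforms of
individual features, so the log adds nothing while compressing dynamic
range for no benefit. Variance uses the population convention (divide by
$S$); windows have fixed length, so the choice only rescales features by
a constant, and the population form is the direct second moment of the
projected signal.

## The boosted-tree classifier

The classifier is a from-scratch multiclass gradient-boosted tree
ensemble in the LightGBM family of designs: feature values are
discretized once into at most `k_bins` quantile bins (default 255), each
tree node accumulates per-bin gradient/hessian/count sums in one pass,
and split search scans bin boundaries maximizing

$$\text{gain} = \frac{G_L^2}{H_L+\lambda} + \frac{G_R^2}{H_R+\lambda}
  - \frac{G^2}{H+\lambda},$$

with both children required to hold at least `min_leaf` samples (ties
break to the lowest feature, then the lowest bin). Trees grow *leafwise*:
at every step the leaf with the globally highest positive gain anywhere
in the tree is split, which spends a fixed leaf budget where it reduces
loss most, and a `max_depth` cap (default 8) prevents the pathologically
deep chains leafwise growth can otherwise produce. Histograms of disjoint
sample blocks merge by bin-wise addition, so construction is
sample-partitionable; the implementation is single-threaded but the merge
identity is asserted in the tests.

Multiclass reduction is softmax cross-entropy with one tree per class per
round: gradient $p_i - y_i$, hessian $p_i(1-p_i)$, base scores equal to
log class priors (an empty ensemble therefore predicts the training
priors). Leaf weights are $-G/(H+\lambda)$, shrunk by `learning_rate`
at accumulation.

Defaults, chosen once as conventional values for this family of models
and all configurable through `lightfd_params()`:
`num_trees = 100` rounds, `num_leaves = 31`, `learning_rate = 0.1`,
`max_depth = 8`, `k_bins = 255`, `lambda_l2 = 0`, `min_leaf = 20`.
Smaller learning rates with more trees buy accuracy at linear cost in
time. Training is deterministic — full-sample boosting, no row or feature
subsampling — so identical inputs give bit-identical serialized models;
gradient one-side sampling, feature bundling, categorical splits and
early stopping are deliberately out of scope.

## Preprocessing choices

* **Filter**: 4th-order Butterworth, 1–40 Hz, applied forward–backward
  (zero phase). Phase distortion would rotate energy between samples and
  corrupt the covariance structure CSP consumes. Channels are demeaned
  and padded by odd reflection (three low-edge periods) before
  `filtfilt`, so no edge transient reaches the retained samples.
* **Epoching**: consecutive non-overlapping 0.5 s windows
  (`round(fs × window)` samples; 128 at 256 Hz); a trailing partial
  window is discarded, all-zero epochs are rejected. Files are assumed to
  contain a single stage per recording; epochs never straddle stage
  boundaries by construction.
* **Artifact rejection** (ICA for ocular artifacts) is out of scope: the
  loader accepts recordings cleaned by any external tool, and the
  synthetic data contain no artifacts.
* Re-referencing is assumed already applied in the input file.

## The synthetic generator

`make_class_covariances()` builds three SPD templates
$\Sigma_c = A D_c A^\top$ sharing one random orthogonal basis $A$, with
geometrically decaying eigenvalue profiles (a coarse stand-in for the
1/f-like EEG spectrum) in which each class boosts a disjoint block of
three basis directions by $1 + 6 \cdot \text{separation}$. At
`separation = 0` the classes coincide; at 1 each class's dominant spatial
direction is orthogonal to the others'. Templates are normalized to unit
mean channel variance, so `noise_std` is interpreted on that scale.

`simulate_subject()` perturbs every template by a per-subject congruence
$\Sigma_c^{(s)} = J_s \Sigma_c J_s^\top$ with
$J_s = I + \text{jitter} \cdot R$ ($R$ standard normal), emulating
electrode-placement and anatomical differences while preserving positive
definiteness, then draws epochs as zero-mean Gaussian noise that is white
in time and colored in space, plus white sensor noise. An optional
`oscillatory` mode modulates the sources with a 10 Hz (alpha-band)
envelope for visual realism.

Defaults — the study conditions for all end-to-end checks, fixed once:
15 channels, 256 Hz, 0.5 s windows, 200 epochs/class/subject, 10
subjects, `separation = 0.8`, `subject_jitter = 0.1`,
`noise_std = 0.3`.

What the generator emulates is exactly the second-order structure CSP
assumes: class-conditional spatial covariance with subject variability.
What it does *not* emulate: non-stationarity within epochs, 1/f temporal
spectra, artifacts, volume-conduction forward models, label noise, or
class imbalance. Passing the end-to-end checks therefore demonstrates
that the machinery is correct and that the protocols rank as expected
under the generative assumptions — not that any particular accuracy
carries over to real recordings.

## Evaluation protocols

* **Intra-subject**: per subject, a stratified-by-class random 80/20
  split (4:1 up to rounding per class), pipeline fit on the training
  split only; reports per-subject accuracies, their mean and their
  *population* variance (the convention matching a table of per-subject
  values). Subjects lacking a class are excluded with a warning.
* **Inter-subject**: all subjects pooled, one stratified 80/20 split,
  overall and per-class accuracies.
* **Transfer**: the full pipeline — CSP projection, bin edges, classifier
  — is fit on the training subjects only and scored on held-out subjects,
  either on a fixed schedule or on random folds (default 2 held-out
  subjects per fold). Refitting CSP inside every training split, in all
  protocols, is a deliberate no-leakage rule; the test suite asserts the
  fitted state is bit-identical before and after predicting perturbed
  test data.

Splits are stratified by class even though a plain random split is the
simpler reading of an 80/20 protocol: at small per-class counts an
unstratified split can empty a class from the test set and make
per-class accuracy undefined.

## Numerical conventions and degenerate inputs

* Covariances are symmetrized (`(C + C')/2`) after every product;
  whitening refuses composites whose smallest eigenvalue falls below
  `1e-10` of the largest (duplicated or silent channels).
* The complementarity $\lambda_d + \lambda_t = 1$ is verified to `1e-8`
  at construction and refused otherwise.
* All-zero epochs raise a degenerate-input error at covariance time and
  are dropped at segmentation time.
* Bin edges are midpoints between distinct values when a feature has at
  most `k_bins` distinct values (binned search is then exact; the suite
  checks equality against an exhaustive presorted oracle), quantile cuts
  otherwise. A sample falls in bin $b$ iff
  $\text{edge}_{b-1} < x \le \text{edge}_b$.
* Split ties break deterministically (lowest feature, then lowest bin);
  leaf-pool ties break to the earliest-created leaf.
* Models serialize to JSON with 17 significant digits, which round-trips
  IEEE doubles exactly; reloaded models predict bit-identically.

## Problem sizes used in the shipped checks

The end-to-end closure check runs the full pipeline on the default
10-subject study (6,000 epochs) for 5 independent seeds, with a
60-round classifier and 5 leave-2-subjects-out folds per seed — sizes
chosen to exercise every code path at full data scale while keeping a
complete suite run in the minutes range on one core. The acceptance
script (`scripts/acceptance.R`) uses the same study conditions for one
seed and additionally reports the pooled inter-subject accuracy.

## Known limitations

* The generator's Gaussian, temporally white epochs are a deliberately
  minimal model; realistic spectra would not change the covariance
  mathematics but would change absolute accuracies.
* One-vs-rest is one of two defensible readings of the triclass
  construction; the alternative contrast is provided but has received
  less tuning attention.
* The booster handles numeric features only, and multiclass problems up
  to the number of classes present in the labels; there is no missing-
  value routing.
* EDF support covers the common single-rate, 16-bit integer layout; the
  annotations extension is not parsed.
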