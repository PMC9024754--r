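---
title: "Retention-index prediction for TMS derivatives: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-index prediction for TMS derivatives: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted GC–MS metabolomics identifies a compound by matching two
orthogonal properties against reference data: its mass spectrum and its
retention behaviour, the latter expressed as a retention index (RI)
relative to co-injected standards. Metabolites are trimethylsilylated
before analysis, so a single metabolite appears as several TMS derivatives
that differ in the number of protected hydroxyl, carboxyl, amino or thiol
groups — and most of these derivatives have no reference RI anywhere.
`tmsri` implements a machine-learning framework for predicting the RI of
TMS derivatives from their structure, for calibrating how much a
prediction can be trusted, and for measuring what predicted RI contributes
to candidate identification when a monoisotopic mass (chemical ionisation,
CI) or a fragment spectrum (electron impact, EI) matches several library
entries.

## Models

### Fingerprint regression

A derivative's structure is encoded as a fixed-length binary fingerprint;
the default is a circular fingerprint of diameter 4 (ECFP-class, radius 2)
folded to 1024 bits, generated by OpenBabel. Alternative classes
(`ecfp2`, `path_fp2`, `maccs`, `pubchem_like`, `layered`) expose the
well-documented sensitivity of prediction accuracy to the encoding: the
same regression on a different fingerprint class gives measurably
different errors, so the class is an explicit, reported configuration
choice rather than a constant.

The regression backend is interchangeable behind a single contract
(`fit(x, y)` / `predict(handle, x)`). Shipped backends: support vector
regression with a linear kernel (the default and the recommended model),
SVR with a polynomial kernel, random forest, and a mean-only baseline that
anchors every comparison. Deep backends (`dnn`, `cnn`) are a plug-in
interface only — `register_ri_backend()` accepts any pair of functions —
because no pre-specified architecture belongs in the core.

Targets are multiplied by 10 before fitting and predictions divided by 10
on the way out; the model handle records the scaling so callers only ever
see RI units. For the SVR backends the cost parameter defaults to 1000
with `epsilon = 0.1` on the scaled targets. This default matters: binary
fingerprint features are left unscaled, so with targets in the thousands
the margin penalty at small cost values dominates the loss and the fitted
function collapses toward its intercept — training error stays far above
the noise floor, i.e. plainly underfitted. Cost 1000 is the smallest order of magnitude at
which training error reaches the noise floor, i.e. the model is allowed to
interpolate its training set; accuracy then comes from interpolation
between structurally similar training molecules, which is also the regime
the similarity-conditioned error calibration (below) describes.
Hyperparameters remain overridable per call.

### Evaluation protocol

Small libraries make single train/test splits noisy, so evaluation uses
repeated random splits: 20 independent 75/25 partitions at record level,
drawn once from the split plan's seed and then reused identically by every
backend. Pooled test-set predictions across all repeats are therefore
paired by (record, split) between any two backends, which is what makes
the paired Wilcoxon comparison in `compare_models()` valid. With 20
repeats a record is left out of every test set with probability
0.75^20 ≈ 0.003, so the pooled evaluation effectively covers the library.
Splitting at record level means the TMS siblings or a stereoisomer twin of
a test record may sit in the training set; that leakage is deliberate —
real libraries contain exactly such near-duplicates, and the
similarity-conditioned analysis quantifies their effect instead of hiding
it.

### The TMS-counterpart shift

Derivatives of the same metabolite with n and n+1 TMS groups elute a
nearly constant relative distance apart, so an ordinary least-squares line
through (RI at n TMS, RI at n+1 TMS) pairs predicts one derivative from
the other in either direction (the inverse direction applies the algebraic
inverse of the line). This two-parameter baseline is surprisingly
competitive and bounds what the fingerprint model must beat for
metabolites that already have one known derivative. Pair levels 1→2 and
2→3 are the well-populated ones in practice and are the exposed defaults;
other levels are available via the `n_low` argument. The error protocol
for the shift model is leave-one-out over pairs, which suits the small
pair counts and makes no further modelling assumptions.

### Similarity-conditioned error (CPF)

Prediction error depends strongly on whether the query resembles the
training set. Each test prediction is keyed by its maximum Tanimoto
similarity to the training records and routed into five similarity ranges
([0.9,1], [0.8,0.9), [0.7,0.8), [0.6,0.7), [0,0.6); lower edges closed).
The empirical cumulative distribution of each range's observed relative
errors becomes the confidence estimator: `error_probability(cpf, s, t)` is
the fraction of that range's errors strictly below `t` ("strictly" follows
the estimator's definition of P(error < t); a switch makes it inclusive).
The CPF uses the raw step function — no smoothing, no parametric model —
because any interpolation would be an additional assumption the data need
not support. All available errors feed the CPF; the equal-size
`balanced_subsample()` is applied only for between-range hypothesis tests,
where unequal group sizes would bias the comparison. Only the maximum
similarity is used, not the whole neighbourhood; conditioning on several
neighbours is a known possible refinement and deliberately out of scope.

### Candidate ranking and filtering

`build_candidate_sets()` simulates the identification setting: seed
records drawn uniformly, expanded by their potential interfering
metabolites — records within 10 ppm of the seed's monoisotopic mass (CI)
or above 0.8 cosine spectral similarity (EI) — with the model trained on
everything outside the candidate sets. The seed's library RI stands in for
the experimental RI. Candidates are ranked by relative predicted-RI error;
exact ties resolve *against* the true identity, so identical structures
can never flatter the ranking. Filtering sweeps a 0–100% error threshold
in 1% steps; a candidate is retained when its error is at or below the
threshold, giving the confusion counts and the ROC curve (trapezoid AUC).
TPR and FPR follow their standard definitions. Single-candidate sets count
for coverage and confusion accounting but are excluded from the
rank-distribution summaries, where they would be trivial wins.

## The synthetic benchmark

`generate_library()` produces a library with known ground truth that
exercises every part of the framework without any download. What it
emulates, and what it does not, determines what passing tests mean.

Base metabolites are small, densely functionalised molecules: linear or
branched C4–C8 skeletons carrying 2–4 groups from {hydroxyl, amino,
carboxyl, thiol}, drawn in structural *families* — a parent plus
descendants created by single edits (extend/shrink the chain, move a
group, swap a group type, toggle a methyl branch). Every derivatization
level from 0 TMS to full protection is emitted per base, mirroring how
curated libraries list each metabolite at several TMS counts.

The latent RI of a base combines:

* a fragment-additive part — offset 400, 55 per skeleton carbon, 15 per
  methyl branch, and a weight per functional group (hydroxyl 80, amino 60,
  carboxyl 150, thiol 90), all in RI units and all arbitrary synthetic
  constants;
* a positional contribution per substituent that depends on its depth from
  the nearer chain end, saturating at depth 3 (terminal vs internal
  substitution separates clearly; interior positional isomers nearly
  co-elute), sd 20 RI;
* a proximity contribution for substituent pairs within three bonds
  (intramolecular interaction stand-in), sd 12 RI;
* a family residual that performs a random walk along the edit tree
  (sd 20 RI per edit).

Each TMS group multiplies the latent RI by 1.055, matching the 5–6%
relative step observed between TMS counterparts; the stored RI adds
Gaussian measurement noise (sd 10 RI, giving an irreducible median
relative error below 1%).

The family residual is the load-bearing design choice. It is the part of
RI that fragment-additive reasoning cannot express, so a model can recover
it only from structurally close training molecules. This is what makes
prediction error *decay* with training-set similarity, the qualitative law
the similarity-conditioned calibration is built on; libraries of
independent, unrelated structures provably do not show the law under a
linear model, because nothing links a query's unlearnable component to its
near neighbours. The positional saturation and the three-bond proximity
cutoff keep those effects largely visible to a radius-2 circular
fingerprint; without the cutoffs they act as unlearnable noise and degrade
accuracy without adding realism.

A fraction of bases (10%) is duplicated under a new identifier as a
stereoisomer stand-in — identical SMILES, hence a Tanimoto = 1 peak in the
pairwise-similarity distribution — with a small RI offset (sd 12 RI),
since real stereoisomer pairs resolve on a GC column. Isobar structure
comes from two sources: natural formula collisions inside families
(moving a group preserves the formula) and engineered partners (15% of
bases, plus every twinned base) built with the same formula but a
different skeleton, optionally trading a methyl branch against a chain
carbon. Partners carry an independent residual (sd 2× the edit walk), so
same-mass candidates are separated by more than the model's typical error
— without this, two-candidate mass collisions would be dominated by
near-co-eluting pairs that no RI model can rank.

Pseudo-EI spectra hash each skeleton carbon's local environment
(substituent and TMS state at the carbon and its two neighbours) to an
m/z bin in 50–500 Da with a lognormal intensity, add coarse
functional-group and chain-length marks, and give every derivatized record
the characteristic TMS fragments at m/z 73 and 147. Shared local
environments mean shared peaks, so cosine spectral similarity tracks the
same structural overlap a circular fingerprint encodes — the statistical
property the EI scenario needs — while nothing about real electron-impact
fragmentation chemistry is simulated. The synthetic spectral clusters run
larger than those of curated libraries, so EI candidate simulations
default to fewer seed metabolites (20) than a real-library protocol would
use, keeping the training set above the 80% coverage floor.

What passing tests on this benchmark do **not** show: accuracy on real
libraries (real structure–retention relationships are richer than a
fragment-additive model with hashed corrections), real EI spectra, RI
calibration transfer between instruments, or the behaviour of commercial
fingerprint software.

## Numerical choices and degenerate inputs

* Tanimoto similarity of two all-zero fingerprints is defined as 1
  (identical absence); zero against non-zero is 0.
* The median of an even-length sample is the midpoint of the two central
  order statistics (R's default).
* Paired Wilcoxon comparisons drop zero differences; if every pair ties,
  the p-value is reported as 1. The normal approximation is used
  throughout (`exact = FALSE`).
* `make_splits()` sizes the training set as `round(0.75 n)`; partitions
  are drawn independently per repeat from seeds derived off one plan seed,
  so a plan reproduces its splits exactly across sessions and backends.
* Fingerprints are generated by the OpenBabel executable in a short-lived
  subprocess (FPS output, byte-order mapped, verified bit-for-bit against
  the in-process OpenBabel API in the test suite); the in-process circular
  fingerprint path retains per-molecule allocations that add up to
  gigabytes over library-sized batches.
* Degenerate shift fits (all `ri_low` equal) and empty similarity ranges
  are errors, not NA results; an unqueryable CPF range reports that more
  data are needed rather than extrapolating from a neighbouring range.
* All randomness flows from explicit integer seeds through an exact-range
  seed-derivation function, so every pipeline stage is independently
  reproducible and two runs from one configuration produce byte-identical
  artifacts.

## Problem sizes

The shipped evaluation uses a 250-base synthetic library (roughly 1,300
derivative records), 20 random 75/25 splits, and 20 repetitions of each
candidate-identification scenario; the test suite exercises the same code
paths on smaller libraries (30–120 bases). These sizes give stable pooled
medians (n ≈ 6,700 pooled test predictions) while keeping a full run in
the minutes range on a single core.

## Known limitations

* The fragment grammar is acyclic C/H/N/O/S(+Si) only — no rings, no
  aromatics, no phosphates or sugars-as-such; structural diversity is
  deliberately narrower than any real metabolome.
* The CPF conditions on the single most similar training molecule;
  neighbourhood-weighted variants could calibrate better.
* OpenBabel's circular fingerprints ignore stereochemistry, so
  stereoisomer stand-ins are indistinguishable to every model here — as
  they are to any 2D-fingerprint model.
* `svm_poly` and `random_forest` ship with fixed sensible defaults; no
  hyperparameter search machinery is included, by design.
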