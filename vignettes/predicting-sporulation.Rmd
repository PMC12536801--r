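---
title: "Predicting sporulation potential from gene content: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sporulation potential from gene content: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endospore formation is a survival program of the Firmicutes (Bacillota):
under stress, Bacilli and Clostridia can package their chromosome into a
dormant, highly resistant spore. Whether an uncultivated organism — known
only through a metagenome-assembled genome (MAG) — can sporulate is hard to
establish experimentally, but the sporulation program leaves a genomic
fingerprint: a characteristic repertoire of genes spanning initiation
(Spo0A phosphorelay and checkpoints), engulfment, the compartment-specific
sigma-factor regulons (SigF, SigE, SigG, SigK), cortex and coat assembly,
and germination machinery.

`sporecast` turns that fingerprint into a calibrated probability. Each
genome is encoded as a binary vector over a fixed catalog of 160
sporulation-associated genes, recognized in functional annotation tables by
gene name or KEGG Orthology (KO) identifier. A stacked ensemble — random
forest and RBF support vector machine base learners feeding a
random-forest meta-classifier — maps that vector to a probability of the
Sporulating phenotype.

## The model

**Feature encoding.** A catalog gene is *present* in a genome if any
annotation row matches it by `Preferred_name` (case-insensitive,
alias-aware) or by a shared KO identifier; multiplicity is ignored and
anything unmatched encodes as absent (0). Absence of evidence is treated
as absence of the gene — appropriate for high-quality genomes, and the
reason MAG completeness matters for interpretation (see *Limitations*).

**Base learners.** Both are tuned by stratified 10-fold cross-validation
with mean out-of-fold area under the ROC curve (AUC) as the selection
metric; ties go to the simpler model.

* Random forest: 500 trees, `mtry` tuned over {2, 3, 4}.
* SVM with radial kernel `K(x, z) = exp(-sigma * ||x - z||^2)`, `sigma`
  fixed at 0.0378 (the kernel-width convention in which that constant is
  meaningful multiplies the squared Euclidean distance; binary inputs are
  not rescaled). Cost is tuned over
  {0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128}; probabilities come from
  Platt-type sigmoid calibration fit within each training fold.

Two further classifiers are kept for comparison, not stacking: gradient
boosting (learning rate 0.1, depth 6, subsampling 0.8 by row and column,
at most 100 rounds with early-stopping patience 10 on an internal
stratified 10% validation split) and a single-hidden-layer perceptron
(width tuned over {1, 3, 5, 7, 9} by repeated 10-fold CV, 3 repeats, at
most 200 backpropagation iterations).

**Stacking.** The meta-classifier is a random forest (`mtry` tuned over
{1, 2}) over exactly two meta-features: the base models' probabilities of
Sporulating. Meta-features for meta-training are strictly *out-of-fold*:
each training genome is scored only by base models fit on folds that
exclude it. The one-line description "base probabilities become
meta-features" would also permit self-scoring by refit base models; that
variant leaks the training labels into the meta-features and can make a
random-label dataset look learnable, so the out-of-fold construction is
enforced by design and by an anti-leakage test (label-permuted cohorts
must yield near-chance test AUC). For deployment, both bases are refit on
all training rows; the manifest records this.

**Decision rule.** `Sporulating` iff probability ≥ 0.5, with ≥ breaking
the boundary case; the threshold is configurable and recorded in the
bundle manifest.

## Evaluation

Six metrics are reported with Sporulating as the positive class:
accuracy, AUC (Mann–Whitney concordance, ties counted ½), recall,
specificity, precision, F1. Undefined ratios (zero denominators) are
reported as missing and excluded from summaries with a logged count,
rather than poisoning medians as NaN.

Uncertainty comes from a non-parametric bootstrap (default 300
iterations): each iteration resamples the *training* set with replacement
— stratified, preserving class counts so no resample collapses to one
class — retrains, and evaluates on the fixed, untouched test split;
per-metric medians and percentile 2.5/97.5 intervals summarize the
iterations. This retrain-on-resample reading is the only one under which
test-set metrics like specificity acquire confidence intervals.
Hyperparameters are tuned once on the original training split and held
fixed across bootstrap iterations (including the meta-forest `mtry`): the
bootstrap quantifies fit variability under training-set perturbation, not
repeated model selection, which would multiply cost ~30-fold for little
inferential gain.

## Interpretation

Gene attributions are Shapley values of the predicted Sporulating
probability with respect to feature presence, estimated by a
model-agnostic permutation-sampling scheme so the same estimator serves
both base models (comparability across models is the point of the
consensus rule). For each explained genome the estimator draws random
feature orderings and walks from a background genome to the explained one,
crediting each gene with the induced change in model output. The sampling
budget (default 2 × 160 orderings per genome) is rounded up to whole
passes over the background set; with whole passes the telescoping sum
makes the attribution *exactly* additive,
`base_value + sum(values) = f(x)`, with `base_value` the mean prediction
over the background. Accuracy against exhaustive 2^d coalition
enumeration is verified for small d in the test suite. The background
defaults to the training matrix; Shapley values are background-dependent,
so the background is configurable and recorded.

Two gene reports follow:

* **Consensus genes** — genes whose *mean signed* contribution is strictly
  positive in both the RF and the SVM attributions ("positive predictor"
  is operationalized as the weakest reading consistent with positivity),
  ranked by the average of the two models' mean absolute attributions.
* **Core genes** — genes present in every genome of a stated group,
  typically all predicted spore-formers, with stage annotations from the
  catalog; per-gene presence counts and per-stage gene-content profiles
  accompany them.

## Ordination and dispersion

Presence/absence structure is summarized three ways. (1) Centered,
unscaled PCA of the 0/1 matrix, with a deterministic sign convention
(largest-magnitude loading positive) so scores are reproducible across
row orders. (2) Binary (Jaccard) distance — discordant over informative
positions, with an all-zero pair defined as distance 0. (3) Multivariate
dispersion: principal-coordinates embedding of the distance matrix,
per-genome distance to its group centroid combining positive- and
negative-eigenvalue axes as `d² = d²_pos − d²_neg` (floored at 0), and a
one-way ANOVA F on those distances. The centroid (not spatial-median)
definition follows the stated dispersion concept. Significance uses label
permutation of the *precomputed* distances (default 1000 permutations),
`p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`; recomputing centroids
within each permutation is a defensible alternative scheme, but the
fixed-distance scheme is the cheaper standard and is the one implemented.

## The synthetic cohort

Everything above is testable offline through a generator that emulates
the statistical structure the classifier assumes — not real genomes. The
default configuration is the study condition set: 68 sporulating + 68
non-sporulating genomes over the 160-gene catalog; 20 informative genes
present with probability 0.9 in spore-formers vs 0.1 otherwise; remaining
genes are noise at 0.2; 5% dropout flips present genes of spore-formers
to absent, modeling genome incompleteness asymmetrically (assembly loses
genes, it never invents them); informative genes are taken block-wise
from the catalog's stage categories and co-occur within a block with
pairwise correlation ≈ 0.3 via a shared latent Bernoulli copied with
probability √0.3 — sporulation genes co-occur by regulon, and tests must
not assume feature independence. Presence probabilities and the
correlation level are the package's own choices of a realistic regime
(strong but imperfect gene–phenotype association, moderate regulon
coupling); they are fixed defaults, not fitting knobs. A companion
generator emits near-empty profiles (per-gene stray probability 0.01)
emulating genomes outside the spore-forming phylum, and an annotation
writer emits eggNOG-mapper-dialect files (name-path or KO-only-path rows
plus decoys) that round-trip exactly through the parser and encoder.

What passing these tests shows: the pipeline recovers planted signal,
refuses permuted labels, scores near-empty genomes as non-sporulating,
and is deterministic under a seed. What it cannot show: performance on
real annotation noise, phylogenetic correlation between genomes
(simulated genomes are exchangeable within class), class-specific gene
repertoires (Bacilli- vs Clostridia-specific regulators), or the true
discriminative geometry of the real 160-gene catalog — the bundled
catalog is a deterministic synthetic stand-in (25 symbols named in the
sporulation literature plus fillers, synthetic K9xxxx KO block) to be
replaced by a curated catalog TSV where available.

## Numerical choices and degenerate inputs

* All tuning grids are closed; a tie in CV AUC selects the smaller
  `mtry`/cost/width (determinism where selection is otherwise arbitrary).
* Stratified partition sizes use the ceiling rule per class
  (e.g. 68 → 48 train at 70%).
* Folds are dealt round-robin within class after shuffling; fold draws
  that leave a fold single-class are redrawn (up to 10 attempts) before
  erroring.
* Constant-feature or otherwise degenerate training data still fit
  (probabilities near the class prior); empty confusion denominators give
  missing values, never NaN.
* A prediction request whose matrix shares fewer than half the catalog
  genes is refused as a suspected wrong matrix; missing catalog genes are
  zero-filled with a warning, unknown columns dropped with a warning.
* One user seed drives every stage through a fixed integer derivation;
  identical seeds give identical artifacts, and the model bundle verifies
  content checksums on reload.
* Default problem sizes throughout the test suite are the study-scale
  cohort (136 × 160) for end-to-end properties and smaller draws for
  per-operation checks; the acceptance script runs the full default
  conditions with a 300-iteration bootstrap and summarizes attributions
  over a balanced 16-genome subset of the held-out split (attribution
  cost scales linearly in explained genomes; the consensus ranking
  averages per-gene statistics and stabilizes well below the full split
  size).

## Limitations

Predictions are gene-content inferences, not phenotype measurements;
incomplete MAGs bias toward absence calls and therefore toward the
non-sporulating class — the dropout parameter exists precisely to probe
that failure mode. The classifier is trained for Firmicutes-style
repertoires; outside that phylum the expected behavior is a near-zero
probability, not a meaningful ranking. The synthetic catalog's KO
identifiers are placeholders: real annotation matching requires a curated
catalog with true KO mappings.
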