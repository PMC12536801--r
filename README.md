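# sporecast

Predict the sporulation potential of bacterial genomes and
metagenome-assembled genomes (MAGs) from the presence or absence of
sporulation-associated genes.

## Why

Endospore formation lets Firmicutes (Bacillota) persist through heat,
desiccation, and transit between hosts, but most candidate spore-formers
are uncultivated: their phenotype cannot be tested in the lab. What a MAG
*does* expose is its gene content. Sporulation leaves a broad genomic
fingerprint — initiation and checkpoint genes, the Spo0A regulon,
engulfment machinery, the SigF/SigE/SigG/SigK regulons, cortex and coat
assembly, germination receptors — and `sporecast` turns that fingerprint
into a calibrated probability of the Sporulating phenotype. Intended
users: microbiome researchers annotating MAG collections, and anyone
screening draft or complete genomes for spore-forming potential
(probiotic discovery, food safety, surveillance).

## What it does

1. **Encode.** Parse eggNOG-mapper-style annotation tables and encode each
   genome as a binary vector over a fixed 160-gene catalog, matching by
   gene name (case-insensitive, alias-aware) or KEGG Orthology identifier.
   Missing evidence encodes as absence.
2. **Classify.** A stacked ensemble: tuned random forest
   (`mtry` ∈ {2,3,4}, 500 trees) and RBF SVM
   (`K(x,z) = exp(−σ‖x−z‖²)`, σ = 0.0378, cost ∈ {0.25, …, 128}) base
   learners, whose out-of-fold probabilities feed a random-forest
   meta-classifier (`mtry` ∈ {1,2}); all selection by stratified 10-fold
   CV AUC. Gradient boosting and a single-hidden-layer neural network are
   available for comparison.
3. **Evaluate.** Six metrics (accuracy, AUC, recall, specificity,
   precision, F1) with medians and percentile 95% CIs from a 300-iteration
   stratified bootstrap of the training set, evaluated on a fixed test
   split; a five-model comparison report.
4. **Interpret.** Sampling-based Shapley attributions for both base
   models, a dual-model positive-consensus gene rule, core genes of
   predicted spore-formers, and stage-resolved gene-content profiles.
5. **Ordinate.** PCA of presence/absence profiles, binary (Jaccard)
   distances, and multivariate dispersion (distance to group centroid in
   principal-coordinates space) with permutation ANOVA.
6. **Simulate.** A synthetic-cohort generator (default: 68 sporulating +
   68 non-sporulating genomes, 20 informative genes at 0.9 vs 0.1
   presence, stage-block correlation 0.3, 5% dropout) plus annotation-file
   emission, so the entire pipeline is testable offline.

The bundled catalog is a deterministic **synthetic** stand-in (25 gene
symbols named in the sporulation-genomics literature plus fillers, with
placeholder KO ids); supply a curated catalog TSV
(`gene_symbol  ko_ids  aliases  stage`) for real annotation work.

## Worked example

```r
library(sporecast)
library(dplyr)

# a labeled cohort with known planted signal (136 genomes x 160 genes)
sim  <- simulate_genomes(simulation_config(seed = 1))
part <- stratified_partition(sim, 0.7, seed = 1)   # 48+48 train / 20+20 test
train <- filter(sim, genome_id %in% part$train)
test  <- filter(sim, genome_id %in% part$test)

fit <- train_ensemble(train, cv_config(seed = 1))
fit
#> <spore_ensemble> stacked RF + SVM with RF meta-classifier
#>   rf: mtry=2 (cv_auc=0.987) | svm: C=0.25 (cv_auc=0.973) | meta mtry=2
#>   trained on 96 genomes over 160 genes; threshold=0.5

predict(fit, test) |>
  inner_join(test[c("genome_id", "phenotype")], by = "genome_id") |>
  with(evaluate_predictions(prob_sporulating, phenotype))
#> # A tibble: 1 × 6
#>   accuracy   auc recall specificity precision    f1
#>      <dbl> <dbl>  <dbl>       <dbl>     <dbl> <dbl>
#> 1     0.95 0.992   0.95        0.95      0.95  0.95
```

The prediction table reports, per genome, the ensemble probability of
Sporulating, both base-model probabilities, the thresholded label
(Sporulating iff probability ≥ 0.5), and the number of catalog genes
present — an all-zero genome (e.g. one from outside the phylum) scores a
probability near 0. `shap_values()` + `consensus_positive_genes()` rank
the genes driving those probabilities in both base models;
`core_genes()` lists genes present in every predicted spore-former.

A thin command-line wrapper covers the same pipeline
(`simulate`, `build-matrix`, `train`, `predict`, `compare`, `explain`,
`ordinate`):

```sh
Rscript inst/cli/sporecast simulate --out demo --seed 1 --annotations
Rscript inst/cli/sporecast train --matrix demo/matrix.csv \
    --labels demo/labels.tsv --catalog demo/catalog.tsv \
    --out demo/model --seed 1
Rscript inst/cli/sporecast predict --model demo/model \
    --matrix demo/matrix.csv --out demo/predictions.tsv
```

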