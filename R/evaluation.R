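#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney concordance probability: the fraction of
#' (positive, negative) genome pairs where the positive scores higher, with
#' ties counted one half.
#'
#' @param scores Numeric scores (higher = more likely Sporulating).
#' @param labels Phenotype labels (`Sporulating` / `Non-Sporulating`) or a
#'   logical/0-1 vector marking positives.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels) || is.numeric(labels)) {
    as.logical(labels)
  } else {
    as_phenotype(labels) == positive_class
  }
  stopifnot(length(scores) == length(pos))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Metrics from a confusion table
#'
#' Standard definitions with Sporulating as the positive class:
#' accuracy = (tp+tn)/n, recall = tp/(tp+fn), specificity = tn/(tn+fp),
#' precision = tp/(tp+fp), F1 = 2PR/(P+R). A zero denominator yields `NA`
#' (undefined) rather than NaN propagation; F1 is undefined whenever
#' precision or recall is, or both are zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return One-row tibble with columns `accuracy`, `recall`, `specificity`,
#'   `precision`, `f1`.
#' @export
#' @examples
#' confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("Empty confusion table", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(accuracy = (tp + tn) / total, recall = recall,
         specificity = safe_div(tn, tn + fp), precision = precision,
         f1 = f1)
}

#' Score predictions against known phenotypes
#'
#' Thresholds the probabilities (label Sporulating iff `prob >= threshold`)
#' and returns the six evaluation metrics.
#'
#' @param scores Predicted probabilities of Sporulating.
#' @param labels True phenotypes.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble `accuracy`, `auc`, `recall`, `specificity`,
#'   `precision`, `f1`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  y <- as_phenotype(labels)
  pred_pos <- scores >= threshold
  truth_pos <- y == positive_class
  cm <- confusion_metrics(tp = sum(pred_pos & truth_pos),
                          fp = sum(pred_pos & !truth_pos),
                          tn = sum(!pred_pos & !truth_pos),
                          fn = sum(!pred_pos & truth_pos))
  dplyr::bind_cols(cm[, "accuracy"], tibble(auc = roc_auc(scores, y)),
                   cm[, c("recall", "specificity", "precision", "f1")])
}

metric_names <- c("accuracy", "auc", "recall", "specificity", "precision",
                  "f1")

#' Bootstrap evaluation of a training procedure
#'
#' Resamples the training set with replacement (stratified, preserving the
#' class counts), retrains via `trainer`, and evaluates the six metrics on
#' the fixed, untouched test set; repeated `n_iter` times (default 300).
#' Summaries are per-metric medians with percentile 95% confidence
#' intervals (2.5/97.5). Undefined metric values are excluded from the
#' summaries with a logged count.
#'
#' @param train,test Disjoint labeled feature tibbles.
#' @param trainer A function `(features, seed)` returning a prediction
#'   function `(features) -> probability of Sporulating`; see
#'   [make_trainer()].
#' @param n_iter Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param threshold Decision threshold for the confusion metrics.
#' @return A `spore_bootstrap` object: `summary` tibble (metric, median,
#'   ci_low, ci_high), raw per-iteration `iterations` tibble, and
#'   `n_iterations`.
#' @export
bootstrap_evaluate <- function(train, test, trainer, n_iter = 300, seed = 1,
                               threshold = 0.5) {
  stopifnot(n_iter >= 1)
  if (length(intersect(train$genome_id, test$genome_id)) > 0) {
    stop("Train and test sets must be disjoint", call. = FALSE)
  }
  y <- as_phenotype(train$phenotype)
  cls_idx <- split(seq_len(nrow(train)), y)
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, 7000 + i)
    withr::with_seed(it_seed, {
      take <- unlist(lapply(cls_idx, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
    })
    boot <- train[take, ]
    # resampling duplicates ids; keep them unique for downstream bookkeeping
    boot$genome_id <- make.unique(boot$genome_id, sep = "~")
    predict_fun <- trainer(boot, derive_seed(seed, 8000 + i))
    rows[[i]] <- dplyr::bind_cols(
      tibble(iteration = i),
      evaluate_predictions(predict_fun(test), test$phenotype, threshold))
  }
  iterations <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(iterations, -"iteration",
                              names_to = "metric", values_to = "value")
  n_undef <- sum(is.na(long$value))
  if (n_undef > 0) {
    message(n_undef, " undefined metric value(s) excluded from summaries")
  }
  summary <- long |>
    dplyr::group_by(metric = factor(.data$metric, levels = metric_names)) |>
    dplyr::summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      ci_low = stats::quantile(.data$value, 0.025, na.rm = TRUE,
                               names = FALSE),
      ci_high = stats::quantile(.data$value, 0.975, na.rm = TRUE,
                                names = FALSE),
      .groups = "drop") |>
    dplyr::arrange(.data$metric)
  structure(list(summary = summary, iterations = iterations,
                 n_iterations = n_iter, seed = seed),
            class = "spore_bootstrap")
}

#' @export
print.spore_bootstrap <- function(x, ...) {
  cat("<spore_bootstrap> ", x$n_iterations, " iterations\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Trainer factories for bootstrap evaluation
#'
#' `make_trainer()` tunes an algorithm once on `features` to fix its
#' hyperparameters, then returns a trainer that refits with those fixed
#' parameters on each (resampled) training set — bootstrap iterations
#' re-estimate fit variability, not the model selection.
#'
#' @param algorithm `"rf"`, `"svm_rbf"`, `"xgboost"`, `"mlp"`, or
#'   `"ensemble"` for the stacked classifier.
#' @param features Labeled feature tibble used for the one-off tuning.
#' @param cv A [cv_config()].
#' @return A function `(features, seed) -> (features -> prob)` suitable for
#'   [bootstrap_evaluate()].
#' @export
make_trainer <- function(algorithm, features, cv = cv_config()) {
  if (algorithm == "ensemble") {
    tuned <- train_ensemble(features, cv)
    params <- list(rf = tuned$rf_base$best_params,
                   svm = tuned$svm_base$best_params,
                   meta_mtry = tuned$meta_mtry)
    return(function(boot, seed) {
      bundle <- refit_ensemble(boot, params, cv, seed)
      function(newdata) {
        # predict() sorts by genome_id; restore the caller's row order
        p <- predict(bundle, newdata, type = "prob")
        unname(p[newdata$genome_id])
      }
    })
  }
  tuned <- switch(algorithm,
    rf = tune_random_forest(features, cv),
    svm_rbf = tune_svm_rbf(features, cv),
    xgboost = tune_xgboost(features, cv),
    mlp = tune_mlp(features, cv),
    stop("Unknown algorithm: ", algorithm, call. = FALSE))
  params <- tuned$best_params
  function(boot, seed) {
    xy <- prepare_xy(boot)
    fit <- fit_base(algorithm, xy$X, xy$y, params, seed)
    genes <- colnames(xy$X)
    function(newdata) {
      newdata <- align_to_genes(newdata, genes)
      predict_base(algorithm, fit, feature_values(newdata))
    }
  }
}

#' Five-model comparison report
#'
#' Performs one stratified 70/30 split, tunes each algorithm (random
#' forest, RBF SVM, gradient boosting, neural network, and the stacked
#' ensemble) on the training split, and bootstrap-evaluates each on the
#' fixed test split. The tidy result carries one row per model and metric
#' with the bootstrap median and 95% CI; [format_comparison()] renders the
#' report-style percentage table.
#'
#' @param features Labeled feature tibble.
#' @param cv A [cv_config()].
#' @param n_iter Bootstrap iterations per model (default 300).
#' @param train_fraction Training fraction for the single split.
#' @param seed Integer seed (defaults to the CV seed).
#' @param models Subset of models to run (default all five).
#' @return A `spore_comparison` tibble: `model`, `metric`, `median`,
#'   `ci_low`, `ci_high`; the train/test ids are attached as attributes.
#' @export
compare_models <- function(features, cv = cv_config(), n_iter = 300,
                           train_fraction = 0.7, seed = cv$seed,
                           models = c("rf", "svm_rbf", "xgboost", "mlp",
                                      "ensemble")) {
  part <- stratified_partition(features, train_fraction, seed)
  train <- features[features$genome_id %in% part$train, ]
  test <- features[features$genome_id %in% part$test, ]
  out <- purrr::map(models, function(alg) {
    trainer <- make_trainer(alg, train, cv)
    boot <- bootstrap_evaluate(train, test, trainer, n_iter = n_iter,
                               seed = derive_seed(seed, match(alg, models)))
    dplyr::bind_cols(tibble(model = alg), boot$summary)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "train_ids") <- part$train
  attr(res, "test_ids") <- part$test
  attr(res, "n_iter") <- n_iter
  class(res) <- c("spore_comparison", class(res))
  res
}

fmt_pct <- function(v) sub("\\.0$", "", sprintf("%.1f", 100 * v))

#' Format a model comparison as a percentage table
#'
#' Renders each cell as `"median (ci_low–ci_high)"` in percent with
#' one-decimal rounding, one row per model and one column per metric.
#'
#' @param comparison A `spore_comparison` from [compare_models()].
#' @return A wide tibble of formatted strings.
#' @export
format_comparison <- function(comparison) {
  comparison |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$median), "",
      paste0(fmt_pct(.data$median), " (", fmt_pct(.data$ci_low), "–",
             fmt_pct(.data$ci_high), ")"))) |>
    dplyr::select("model", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
}
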