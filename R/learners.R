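#' Cross-validation configuration
#'
#' Stratified k-fold cross-validation settings shared by all tuning
#' routines. Model selection always uses the mean out-of-fold area under the
#' ROC curve; ties are broken toward the simpler model.
#'
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed driving all randomness downstream.
#' @param repeats CV repeats used where a tuner averages over repeated fold
#'   draws (the neural network tuner; default 3).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 10, seed = 1, repeats = 3) {
  stopifnot(n_folds >= 2, repeats >= 1)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 repeats = as.integer(repeats), stratified = TRUE),
            class = "cv_config")
}

#' Stratified train/test partition
#'
#' Splits labeled genomes into train and test sets per class, taking
#' `ceiling(train_fraction * class size)` genomes of each class for
#' training. Deterministic given the seed.
#'
#' @param features Labeled feature tibble (or any tibble with `genome_id`
#'   and `phenotype`).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` of genome ids.
#' @export
#' @examples
#' sim <- simulate_genomes(simulation_config(seed = 1))
#' part <- stratified_partition(sim, 0.7, seed = 1)
#' length(part$train)  # 48 + 48
stratified_partition <- function(features, train_fraction = 0.7, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- as_phenotype(features$phenotype)
  if (anyNA(y)) stop("All genomes must be labeled", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("Both phenotype classes must be present", call. = FALSE)
  }
  ids <- features$genome_id
  withr::local_seed(seed)
  train <- unlist(lapply(levels(y), function(cl) {
    cl_ids <- ids[y == cl]
    if (length(cl_ids) < 2) {
      stop("Each class needs at least 2 genomes", call. = FALSE)
    }
    sample(cl_ids, ceiling(train_fraction * length(cl_ids)))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

# Stratified fold assignment; each class is shuffled and dealt round-robin.
make_folds <- function(y, n_folds, seed) {
  withr::local_seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  fold
}

# Folds where every fold holds both classes; redrawn up to 10 times.
make_valid_folds <- function(y, n_folds, seed, max_attempts = 10) {
  for (a in seq_len(max_attempts)) {
    fold <- make_folds(y, n_folds, derive_seed(seed, a))
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(y[fold == k])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("Could not draw ", n_folds, "-fold partition with both classes in ",
       "every fold after ", max_attempts, " attempts; reduce n_folds",
       call. = FALSE)
}

prepare_xy <- function(features, cv = NULL) {
  check_binary_features(features)
  if (!"phenotype" %in% names(features)) {
    stop("Training requires a `phenotype` column", call. = FALSE)
  }
  y <- as_phenotype(features$phenotype)
  if (anyNA(y)) stop("All training genomes must be labeled", call. = FALSE)
  if (!is.null(cv)) {
    if (min(table(y)) < cv$n_folds) {
      stop("Need at least n_folds (", cv$n_folds, ") genomes per class",
           call. = FALSE)
    }
  }
  list(X = feature_values(features), y = y)
}

# ---- fitting and prediction dispatch -------------------------------------

svm_sigma_default <- 0.0378

fit_base <- function(algorithm, X, y, params, seed) {
  # a fully constant design carries no information; fall back to the class
  # prior (randomForest does not terminate on such input)
  if (all(X == matrix(X[1, ], nrow(X), ncol(X), byrow = TRUE))) {
    return(structure(list(prior = mean(y == positive_class)),
                     class = "spore_prior_model"))
  }
  withr::local_seed(seed)
  switch(algorithm,
    rf = randomForest::randomForest(
      x = X, y = y, ntree = params$ntree %||% 500L,
      mtry = params$mtry),
    svm_rbf = kernlab::ksvm(
      x = X, y = y, type = "C-svc", kernel = "rbfdot",
      kpar = list(sigma = params$sigma %||% svm_sigma_default),
      C = params$C, prob.model = TRUE, scaled = FALSE),
    xgboost = fit_xgboost(X, y, params, seed),
    mlp = nnet::nnet(
      x = X, y = as.numeric(y == positive_class),
      size = params$size, maxit = params$maxit %||% 200L,
      decay = params$decay %||% 0, entropy = TRUE, trace = FALSE,
      MaxNWts = 100000L),
    stop("Unknown algorithm: ", algorithm, call. = FALSE)
  )
}

fit_xgboost <- function(X, y, params, seed) {
  label <- as.numeric(y == positive_class)
  # internal stratified 10% validation split for early stopping
  withr::local_seed(derive_seed(seed, 17))
  val <- unlist(lapply(c(0, 1), function(cl) {
    idx <- which(label == cl)
    sample(idx, max(1L, floor(0.1 * length(idx))))
  }), use.names = FALSE)
  tr <- setdiff(seq_along(label), val)
  dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = label[tr])
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = label[val])
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "auc",
                  eta = 0.1, max_depth = 6, subsample = 0.8,
                  colsample_bytree = 0.8, nthread = 1,
                  seed = derive_seed(seed, 23)),
    data = dtrain, nrounds = params$nrounds %||% 100L,
    evals = list(val = dval),
    early_stopping_rounds = params$patience %||% 10L, verbose = 0)
}

predict_base <- function(algorithm, fitted, X) {
  if (inherits(fitted, "spore_prior_model")) {
    return(rep(fitted$prior, nrow(X)))
  }
  p <- switch(algorithm,
    rf = stats::predict(fitted, X, type = "prob")[, positive_class],
    svm_rbf = kernlab::predict(fitted, X,
                               type = "probabilities")[, positive_class],
    xgboost = stats::predict(fitted, xgboost::xgb.DMatrix(X)),
    mlp = as.numeric(stats::predict(fitted, X)),
    stop("Unknown algorithm: ", algorithm, call. = FALSE)
  )
  unname(pmin(1, pmax(0, as.numeric(p))))
}

new_spore_model <- function(algorithm, best_params, cv_auc, cv_results,
                            fitted, seed) {
  structure(list(algorithm = algorithm, best_params = best_params,
                 cv_auc = cv_auc, cv_results = cv_results, fitted = fitted,
                 seed = seed),
            class = "spore_model")
}

#' Predict with a tuned base learner
#'
#' @param object A `spore_model`.
#' @param new_data Feature tibble or genomes-by-genes 0/1 matrix with the
#'   training gene columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of Sporulating.
#' @export
predict.spore_model <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) new_data else feature_values(new_data)
  predict_base(object$algorithm, object$fitted, X)
}

#' @export
print.spore_model <- function(x, ...) {
  cat("<spore_model> ", x$algorithm, " | cv_auc=", signif(x$cv_auc, 4),
      " | params: ",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Mean per-fold out-of-fold AUC for one parameter setting.
cv_mean_auc <- function(algorithm, X, y, params, fold, seed) {
  n_folds <- max(fold)
  aucs <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    fit <- fit_base(algorithm, X[tr, , drop = FALSE], y[tr], params,
                    derive_seed(seed, 100 + k))
    roc_auc(predict_base(algorithm, fit, X[!tr, , drop = FALSE]), y[!tr])
  }, double(1))
  mean(aucs)
}

tune_over_grid <- function(algorithm, features, cv, grid, seed_tag) {
  xy <- prepare_xy(features, cv)
  fold <- make_valid_folds(xy$y, cv$n_folds, derive_seed(cv$seed, seed_tag))
  scores <- vapply(grid, function(params) {
    cv_mean_auc(algorithm, xy$X, xy$y, params, fold,
                derive_seed(cv$seed, seed_tag + 1))
  }, double(1))
  best <- which.max(scores)  # first max: grids are ordered simple -> complex
  fitted <- fit_base(algorithm, xy$X, xy$y, grid[[best]],
                     derive_seed(cv$seed, seed_tag + 2))
  cv_results <- dplyr::bind_cols(
    dplyr::bind_rows(lapply(grid, as_tibble)), tibble(cv_auc = scores))
  new_spore_model(algorithm, grid[[best]], scores[best], cv_results, fitted,
                  cv$seed)
}

#' Tune the random forest base learner
#'
#' Grid search over `mtry` in \{2, 3, 4\} with 500 trees, selecting the
#' value maximizing mean 10-fold CV AUC (ties go to the smallest `mtry`),
#' then refitting on all training rows.
#'
#' @param features Labeled feature tibble.
#' @param cv A [cv_config()].
#' @return A `spore_model`.
#' @export
tune_random_forest <- function(features, cv = cv_config()) {
  grid <- lapply(c(2L, 3L, 4L), function(m) list(mtry = m, ntree = 500L))
  tune_over_grid("rf", features, cv, grid, seed_tag = 1000)
}

#' Tune the RBF support vector machine base learner
#'
#' Radial-basis kernel `K(x, z) = exp(-sigma * ||x - z||^2)` with the kernel
#' coefficient held at `sigma = 0.0378`; grid search over cost
#' `C` in \{0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128\} by mean CV AUC (ties to
#' the smallest `C`). Class probabilities come from Platt-type sigmoid
#' calibration fit within each training fold (`prob.model = TRUE`).
#' Binary inputs are not rescaled, so `sigma` acts on raw presence/absence
#' distances.
#'
#' @inheritParams tune_random_forest
#' @param sigma Kernel coefficient (fixed default 0.0378).
#' @return A `spore_model`.
#' @export
tune_svm_rbf <- function(features, cv = cv_config(),
                         sigma = svm_sigma_default) {
  grid <- lapply(c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128),
                 function(C) list(C = C, sigma = sigma))
  tune_over_grid("svm_rbf", features, cv, grid, seed_tag = 2000)
}

#' Train the gradient-boosting learner
#'
#' Fixed configuration: `eta = 0.1`, `max_depth = 6`, `subsample = 0.8`,
#' `colsample_bytree = 0.8`, at most 100 boosting rounds with early stopping
#' (patience 10) on the AUC of an internal stratified 10% validation split.
#' The reported `cv_auc` is the mean out-of-fold AUC of this configuration
#' under the shared CV scheme.
#'
#' @inheritParams tune_random_forest
#' @return A `spore_model` (its `best_params` records the realized best
#'   boosting round).
#' @export
tune_xgboost <- function(features, cv = cv_config()) {
  params <- list(nrounds = 100L, patience = 10L)
  model <- tune_over_grid("xgboost", features, cv, list(params),
                          seed_tag = 3000)
  best_it <- xgboost::xgb.attributes(model$fitted)$best_iteration
  model$best_params$best_iteration <- as.integer(best_it %||% NA_integer_)
  model
}

#' Tune the single-hidden-layer neural network
#'
#' Feed-forward perceptron with one hidden layer trained by backpropagation
#' for at most 200 iterations. The hidden-layer width is chosen from
#' `hidden_grid` by repeated stratified 10-fold CV AUC (`cv$repeats`
#' repeats, default 3); ties go to the narrowest layer.
#'
#' @inheritParams tune_random_forest
#' @param hidden_grid Candidate hidden-layer widths (default 1, 3, 5, 7, 9).
#' @return A `spore_model`.
#' @export
tune_mlp <- function(features, cv = cv_config(),
                     hidden_grid = c(1L, 3L, 5L, 7L, 9L)) {
  xy <- prepare_xy(features, cv)
  scores <- matrix(NA_real_, cv$repeats, length(hidden_grid))
  for (r in seq_len(cv$repeats)) {
    fold <- make_valid_folds(xy$y, cv$n_folds,
                             derive_seed(cv$seed, 4000 + r))
    scores[r, ] <- vapply(seq_along(hidden_grid), function(j) {
      cv_mean_auc("mlp", xy$X, xy$y,
                  list(size = hidden_grid[j], maxit = 200L), fold,
                  derive_seed(cv$seed, 4100 + r * 10 + j))
    }, double(1))
  }
  mean_scores <- colMeans(scores)
  best <- which.max(mean_scores)
  params <- list(size = hidden_grid[best], maxit = 200L)
  fitted <- fit_base("mlp", xy$X, xy$y, params, derive_seed(cv$seed, 4999))
  cv_results <- tibble(size = hidden_grid, maxit = 200L,
                       cv_auc = mean_scores)
  new_spore_model("mlp", params, mean_scores[best], cv_results, fitted,
                  cv$seed)
}

#' Leakage-free out-of-fold probabilities
#'
#' For each cross-validation fold, fits the given algorithm on the fold's
#' complement and predicts the held-out rows, so every training genome
#' receives exactly one probability from a model that never saw it. Folds
#' where a class is absent are redrawn (up to 10 attempts).
#'
#' @param features Labeled feature tibble.
#' @param algorithm One of `"rf"`, `"svm_rbf"`, `"xgboost"`, `"mlp"`.
#' @param params Parameter list as used by the corresponding tuner.
#' @param cv A [cv_config()].
#' @param fold Optional pre-computed fold assignment (integer vector); when
#'   supplied it is used as-is so several learners can share folds.
#' @return Tibble `genome_id`, `fold`, `prob` (probability of Sporulating),
#'   in the input row order.
#' @export
oof_probabilities <- function(features, algorithm, params,
                              cv = cv_config(), fold = NULL) {
  xy <- prepare_xy(features, cv)
  if (is.null(fold)) {
    fold <- make_valid_folds(xy$y, cv$n_folds, derive_seed(cv$seed, 5000))
  }
  prob <- rep(NA_real_, length(xy$y))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    fit <- fit_base(algorithm, xy$X[tr, , drop = FALSE], xy$y[tr], params,
                    derive_seed(cv$seed, 5100 + k))
    prob[!tr] <- predict_base(algorithm, fit, xy$X[!tr, , drop = FALSE])
  }
  tibble(genome_id = features$genome_id, fold = fold, prob = prob)
}
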