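#' Train the stacked sporulation classifier
#'
#' Trains the two base learners (tuned random forest and RBF SVM), builds a
#' two-column meta-feature table from their strictly out-of-fold
#' probabilities on the training genomes, and tunes a random-forest
#' meta-classifier (`mtry` in \{1, 2\}, 500 trees) on those meta-features by
#' 10-fold CV AUC. Both base learners are refit on all training rows for
#' deployment. Because meta-features are out-of-fold, no base model ever
#' scored a genome it was trained on.
#'
#' @param features Labeled feature tibble aligned to the catalog.
#' @param cv A [cv_config()]; its seed drives all randomness.
#' @param threshold Decision threshold mapping probability to label
#'   (Sporulating iff `prob >= threshold`; default 0.5).
#' @param catalog Optional gene catalog used at encoding time; stored in the
#'   bundle (with its checksum) so predictions can re-align inputs.
#' @return A `spore_ensemble` bundle.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_genomes(simulation_config(seed = 1))
#' part <- stratified_partition(sim, 0.7, seed = 1)
#' fit <- train_ensemble(sim[sim$genome_id %in% part$train, ],
#'                       cv_config(seed = 1))
#' predict(fit, sim[sim$genome_id %in% part$test, ])
#' }
train_ensemble <- function(features, cv = cv_config(), threshold = 0.5,
                           catalog = NULL) {
  xy <- prepare_xy(features, cv)
  rf_base <- tune_random_forest(features, cv)
  svm_base <- tune_svm_rbf(features, cv)
  bundle <- assemble_ensemble(features, rf_base, svm_base,
                              meta_mtry = NULL, cv = cv,
                              threshold = threshold, catalog = catalog)
  bundle
}

# Shared by train_ensemble (tunes meta mtry) and refit_ensemble (fixed).
assemble_ensemble <- function(features, rf_base, svm_base, meta_mtry, cv,
                              threshold, catalog = NULL, seed = cv$seed) {
  xy <- prepare_xy(features, cv)
  fold <- make_valid_folds(xy$y, cv$n_folds, derive_seed(seed, 6000))
  oof_rf <- oof_probabilities(features, "rf", rf_base$best_params, cv,
                              fold = fold)
  oof_svm <- oof_probabilities(features, "svm_rbf", svm_base$best_params,
                               cv, fold = fold)
  meta_features <- tibble(rf_prob = oof_rf$prob, svm_prob = oof_svm$prob)
  meta_X <- as.matrix(meta_features)

  meta_cv <- NULL
  if (is.null(meta_mtry)) {
    meta_fold <- make_valid_folds(xy$y, cv$n_folds, derive_seed(seed, 6100))
    scores <- vapply(c(1L, 2L), function(m) {
      aucs <- vapply(seq_len(cv$n_folds), function(k) {
        tr <- meta_fold != k
        fit <- withr::with_seed(derive_seed(seed, 6200 + 10 * m + k),
          randomForest::randomForest(x = meta_X[tr, , drop = FALSE],
                                     y = xy$y[tr], ntree = 500L, mtry = m))
        roc_auc(stats::predict(fit, meta_X[!tr, , drop = FALSE],
                               type = "prob")[, positive_class], xy$y[!tr])
      }, double(1))
      mean(aucs)
    }, double(1))
    meta_mtry <- c(1L, 2L)[which.max(scores)]
    meta_cv <- tibble(mtry = c(1L, 2L), cv_auc = scores)
  }
  meta <- withr::with_seed(derive_seed(seed, 6300),
    randomForest::randomForest(x = meta_X, y = xy$y, ntree = 500L,
                               mtry = meta_mtry))
  gene_symbols <- colnames(xy$X)
  checksum <- if (!is.null(catalog)) {
    catalog_checksum(catalog)
  } else {
    hash_lines(gene_symbols)
  }
  manifest <- list(
    tool = "sporecast",
    version = as.character(utils::packageVersion("sporecast")),
    seed = cv$seed,
    n_folds = cv$n_folds,
    threshold = threshold,
    n_train = nrow(features),
    class_counts = as.list(table(xy$y)),
    grids = list(rf_mtry = c(2, 3, 4),
                 svm_C = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128),
                 svm_sigma = svm_sigma_default,
                 meta_mtry = c(1, 2)),
    best_params = list(rf = rf_base$best_params,
                       svm = svm_base$best_params,
                       meta_mtry = meta_mtry),
    cv_auc = list(rf = rf_base$cv_auc, svm = svm_base$cv_auc),
    catalog_checksum = checksum
  )
  structure(list(rf_base = rf_base, svm_base = svm_base, meta = meta,
                 meta_mtry = meta_mtry, meta_cv = meta_cv,
                 oof = dplyr::bind_cols(tibble(genome_id =
                                                 features$genome_id),
                                        meta_features),
                 gene_symbols = gene_symbols, catalog = catalog,
                 threshold = threshold, manifest = manifest),
            class = "spore_ensemble")
}

# Refit with fixed hyperparameters (bootstrap path).
refit_ensemble <- function(features, params, cv, seed) {
  xy <- prepare_xy(features)
  rf_base <- new_spore_model("rf", params$rf, NA_real_, NULL,
                             fit_base("rf", xy$X, xy$y, params$rf,
                                      derive_seed(seed, 1)), seed)
  svm_base <- new_spore_model("svm_rbf", params$svm, NA_real_, NULL,
                              fit_base("svm_rbf", xy$X, xy$y, params$svm,
                                       derive_seed(seed, 2)), seed)
  assemble_ensemble(features, rf_base, svm_base,
                    meta_mtry = params$meta_mtry, cv = cv, threshold = 0.5,
                    seed = seed)
}

#' @export
print.spore_ensemble <- function(x, ...) {
  cat("<spore_ensemble> stacked RF + SVM with RF meta-classifier\n",
      "  rf: mtry=", x$rf_base$best_params$mtry,
      " (cv_auc=", signif(x$rf_base$cv_auc, 3), ")",
      " | svm: C=", x$svm_base$best_params$C,
      " (cv_auc=", signif(x$svm_base$cv_auc, 3), ")",
      " | meta mtry=", x$meta_mtry, "\n",
      "  trained on ", x$manifest$n_train, " genomes over ",
      length(x$gene_symbols), " genes; threshold=", x$threshold, "\n",
      sep = "")
  invisible(x)
}

#' Predict sporulation potential
#'
#' Aligns the input matrix to the bundle's gene order (zero-filling missing
#' catalog genes, dropping unknown columns, hard error if fewer than half
#' the genes are present), scores it with both refit base learners, and
#' feeds their probabilities to the meta-classifier.
#'
#' @param object A `spore_ensemble`.
#' @param new_data Feature tibble.
#' @param type `"table"` (default) for the full prediction table, `"prob"`
#'   for a vector of ensemble probabilities.
#' @param ... Unused.
#' @return For `type = "table"`, a tibble sorted by `genome_id` with
#'   columns `genome_id`, `prob_sporulating`, `rf_prob`, `svm_prob`,
#'   `predicted_label`, `n_genes_present`; for `type = "prob"`, a named
#'   numeric vector in the same order.
#' @export
predict.spore_ensemble <- function(object, new_data,
                                   type = c("table", "prob"), ...) {
  type <- match.arg(type)
  new_data <- align_to_genes(new_data, object$gene_symbols)
  new_data <- new_data[order(new_data$genome_id), ]
  X <- feature_values(new_data)
  rf_prob <- predict_base("rf", object$rf_base$fitted, X)
  svm_prob <- predict_base("svm_rbf", object$svm_base$fitted, X)
  meta_X <- cbind(rf_prob = rf_prob, svm_prob = svm_prob)
  prob <- stats::predict(object$meta, meta_X,
                         type = "prob")[, positive_class]
  prob <- unname(as.numeric(prob))
  if (type == "prob") {
    return(stats::setNames(prob, new_data$genome_id))
  }
  tibble(
    genome_id = new_data$genome_id,
    prob_sporulating = prob,
    rf_prob = rf_prob,
    svm_prob = svm_prob,
    predicted_label = factor(
      ifelse(prob >= object$threshold, positive_class, phenotype_levels[1]),
      levels = phenotype_levels),
    n_genes_present = as.integer(rowSums(X))
  )
}

#' Save / load an ensemble bundle
#'
#' The bundle directory holds the serialized base and meta models, the gene
#' order, the catalog (when recorded), and a `manifest.json` with the seed,
#' grids, selected parameters, catalog checksum, threshold, tool version,
#' and per-file checksums. `load_ensemble()` verifies file presence and
#' checksums and refuses tampered or incomplete bundles.
#'
#' @param bundle A `spore_ensemble`.
#' @param dir Bundle directory.
#' @return `dir` invisibly for the saver; the restored `spore_ensemble` for
#'   the loader.
#' @export
save_ensemble <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- list(rf_base = bundle$rf_base, svm_base = bundle$svm_base,
                meta = bundle$meta, meta_mtry = bundle$meta_mtry,
                oof = bundle$oof, gene_symbols = bundle$gene_symbols,
                threshold = bundle$threshold)
  model_path <- file.path(dir, "models.rds")
  saveRDS(parts, model_path, version = 2)
  if (!is.null(bundle$catalog)) {
    write_gene_catalog(bundle$catalog, file.path(dir, "catalog.tsv"))
  }
  manifest <- bundle$manifest
  manifest$files <- list(models.rds = unname(tools::md5sum(model_path)))
  if (!is.null(bundle$catalog)) {
    manifest$files$catalog.tsv <-
      unname(tools::md5sum(file.path(dir, "catalog.tsv")))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("Bundle load error: missing file manifest.json in ", dir,
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      stop("Bundle load error: missing file ", f, call. = FALSE)
    }
    if (!identical(unname(tools::md5sum(p)), manifest$files[[f]])) {
      stop("Bundle load error: checksum mismatch for ", f,
           "; the bundle was modified after saving", call. = FALSE)
    }
  }
  parts <- readRDS(file.path(dir, "models.rds"))
  catalog <- NULL
  if (file.exists(file.path(dir, "catalog.tsv"))) {
    catalog <- read_gene_catalog(file.path(dir, "catalog.tsv"))
  }
  structure(list(rf_base = parts$rf_base, svm_base = parts$svm_base,
                 meta = parts$meta, meta_mtry = parts$meta_mtry,
                 meta_cv = NULL, oof = parts$oof,
                 gene_symbols = parts$gene_symbols, catalog = catalog,
                 threshold = parts$threshold, manifest = manifest),
            class = "spore_ensemble")
}
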