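#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tuned base learner
#'
#' Returns the tuning grid with its cross-validated AUC per candidate.
#'
#' @param x A `spore_model`.
#' @param ... Unused.
#' @return Tibble of grid settings and `cv_auc`.
#' @export
tidy.spore_model <- function(x, ...) {
  out <- x$cv_results %||% tibble(cv_auc = x$cv_auc)
  as_tibble(out)
}

#' @rdname tidy.spore_model
#' @export
glance.spore_model <- function(x, ...) {
  dplyr::bind_cols(tibble(algorithm = x$algorithm, cv_auc = x$cv_auc),
                   as_tibble(x$best_params[!vapply(x$best_params, is.null,
                                                   logical(1))]))
}

#' Tidy a stacked ensemble
#'
#' One row per component model with its selected parameters and CV AUC.
#'
#' @param x A `spore_ensemble`.
#' @param ... Unused.
#' @return Tibble `component`, `parameter`, `cv_auc`.
#' @export
tidy.spore_ensemble <- function(x, ...) {
  meta_auc <- if (!is.null(x$meta_cv)) {
    x$meta_cv$cv_auc[match(x$meta_mtry, x$meta_cv$mtry)]
  } else NA_real_
  tibble(
    component = c("rf_base", "svm_base", "meta"),
    parameter = c(paste0("mtry=", x$rf_base$best_params$mtry),
                  paste0("C=", x$svm_base$best_params$C),
                  paste0("mtry=", x$meta_mtry)),
    cv_auc = c(x$rf_base$cv_auc, x$svm_base$cv_auc, meta_auc))
}

#' @rdname tidy.spore_ensemble
#' @export
glance.spore_ensemble <- function(x, ...) {
  tibble(n_train = x$manifest$n_train,
         n_genes = length(x$gene_symbols),
         rf_mtry = x$rf_base$best_params$mtry,
         svm_C = x$svm_base$best_params$C,
         meta_mtry = x$meta_mtry,
         threshold = x$threshold,
         seed = x$manifest$seed,
         catalog_checksum = x$manifest$catalog_checksum)
}

#' Tidy bootstrap evaluation results
#'
#' @param x A `spore_bootstrap`.
#' @param ... Unused.
#' @return The per-metric summary tibble (median and 95% CI).
#' @export
tidy.spore_bootstrap <- function(x, ...) x$summary

#' @rdname tidy.spore_bootstrap
#' @export
glance.spore_bootstrap <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, seed = x$seed)
}

#' Tidy a dispersion analysis
#'
#' @param x A `spore_dispersion`.
#' @param ... Unused.
#' @return Per-genome distances-to-centroid tibble.
#' @export
tidy.spore_dispersion <- function(x, ...) x$distances

#' @rdname tidy.spore_dispersion
#' @export
glance.spore_dispersion <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' Tidy a presence/absence PCA
#'
#' @param x A `spore_pca`.
#' @param matrix `"scores"` (default), `"loadings"`, or `"eigenvalues"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.spore_pca <- function(x, matrix = c("scores", "loadings",
                                         "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = tibble(component = seq_along(x$percent_variance),
                              percent_variance = x$percent_variance))
}

#' Tidy a Shapley attribution matrix
#'
#' @param x A `spore_shap`.
#' @param ... Unused.
#' @return Long tibble `genome_id`, `gene_symbol`, `shap_value`.
#' @export
tidy.spore_shap <- function(x, ...) {
  tibble(genome_id = rep(x$genome_ids, times = length(x$gene_symbols)),
         gene_symbol = rep(x$gene_symbols, each = length(x$genome_ids)),
         shap_value = as.vector(x$values))
}

#' @rdname tidy.spore_shap
#' @export
glance.spore_shap <- function(x, ...) {
  tibble(model_tag = x$model_tag, base_value = x$base_value,
         n_samples = x$n_samples, n_genomes = length(x$genome_ids),
         n_genes = length(x$gene_symbols))
}
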