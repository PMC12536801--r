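#' Sampling Shapley attribution of model probabilities
#'
#' Model-agnostic estimate of the Shapley value of each gene for each
#' genome's predicted probability of Sporulating, relative to a background
#' expectation. One code path serves every probability model so values stay
#' comparable across the two base learners.
#'
#' The estimator draws random feature orderings; for each ordering and one
#' background genome it walks from the background to the explained genome
#' feature by feature, crediting each gene with the change in the model
#' output. The evaluation budget is rounded up to whole passes over the
#' background set, which makes the attribution exactly additive:
#' `base_value + sum(values[i, ]) == f(x_i)` for every genome, where
#' `base_value` is the mean model output over the background.
#'
#' @param model A `spore_model`, a `spore_ensemble`, or a function mapping a
#'   genomes-by-genes 0/1 matrix to a probability vector.
#' @param features Feature tibble of genomes to explain (aligned).
#' @param background Feature tibble giving the reference distribution
#'   (typically the training matrix).
#' @param n_samples Sampling budget: number of (ordering, background) draws
#'   per genome; default twice the number of genes. A budget below twice the
#'   gene count triggers a loose-accuracy warning. The realized budget is
#'   the smallest multiple of the background size at least this large.
#' @param seed Integer seed.
#' @param model_tag Label stored with the result (e.g. `"rf"`).
#' @return A `spore_shap` object with fields `values` (genomes x genes
#'   matrix), `base_value`, `n_samples`, `model_tag`, `genome_ids`,
#'   `gene_symbols`.
#' @export
shap_values <- function(model, features, background, n_samples = NULL,
                        seed = 1, model_tag = NULL) {
  predict_fun <- as_predict_fun(model)
  if (is.null(model_tag)) {
    model_tag <- if (inherits(model, "spore_model")) model$algorithm else
      "model"
  }
  check_binary_features(features)
  check_binary_features(background, "background")
  X <- feature_values(features)
  B <- feature_values(background)
  if (!identical(colnames(X), colnames(B))) {
    stop("`features` and `background` must share the same gene columns",
         call. = FALSE)
  }
  d <- ncol(X)
  n_bg <- nrow(B)
  if (is.null(n_samples)) n_samples <- 2L * d
  if (n_samples < 2 * d) {
    warning("Sampling budget below 2 x n_genes; attributions will be noisy",
            call. = FALSE)
  }
  n_draws <- as.integer(ceiling(n_samples / n_bg) * n_bg)

  base_value <- mean(predict_fun(B))
  values <- matrix(0, nrow(X), d, dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    withr::local_seed(derive_seed(seed, 9000 + i))
    x <- X[i, ]
    bg_order <- as.vector(replicate(n_draws / n_bg, sample.int(n_bg)))
    ords <- t(replicate(n_draws, sample.int(d)))  # n_draws x d
    # step matrix per draw: row r has the first r-1 ordered features set to x
    big <- matrix(0, n_draws * (d + 1L), d)
    steps <- 0:d
    for (s in seq_len(n_draws)) {
      pos <- integer(d)
      pos[ords[s, ]] <- seq_len(d)
      take <- outer(steps, pos, `>=`)
      b <- B[bg_order[s], ]
      block <- matrix(b, d + 1L, d, byrow = TRUE)
      block[take] <- matrix(x, d + 1L, d, byrow = TRUE)[take]
      big[((s - 1L) * (d + 1L) + 1L):(s * (d + 1L)), ] <- block
    }
    colnames(big) <- colnames(X)
    f <- matrix(predict_fun(big), nrow = d + 1L)  # (d+1) x n_draws
    diffs <- f[-1L, , drop = FALSE] - f[-(d + 1L), , drop = FALSE]
    phi <- rowsum(as.vector(diffs), group = as.vector(t(ords)))
    values[i, ] <- phi[order(as.integer(rownames(phi))), 1] / n_draws
  }
  structure(list(values = values, base_value = base_value,
                 n_samples = n_draws, model_tag = model_tag,
                 genome_ids = rownames(values),
                 gene_symbols = colnames(values)),
            class = "spore_shap")
}

as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "spore_model")) {
    return(function(M) predict_base(model$algorithm, model$fitted, M))
  }
  if (inherits(model, "spore_ensemble")) {
    return(function(M) {
      rf <- predict_base("rf", model$rf_base$fitted, M)
      svm <- predict_base("svm_rbf", model$svm_base$fitted, M)
      unname(stats::predict(model$meta, cbind(rf_prob = rf, svm_prob = svm),
                            type = "prob")[, positive_class])
    })
  }
  stop("Cannot derive a prediction function from this object", call. = FALSE)
}

#' @export
print.spore_shap <- function(x, ...) {
  cat("<spore_shap> ", x$model_tag, ": ", nrow(x$values), " genome(s) x ",
      ncol(x$values), " gene(s), base_value=", signif(x$base_value, 4),
      ", budget=", x$n_samples, "\n", sep = "")
  invisible(x)
}

#' Per-gene Shapley summaries
#'
#' Mean absolute and mean signed attribution per gene over the explained
#' genomes, sorted by descending mean absolute value.
#'
#' @param shap A `spore_shap`.
#' @return Tibble `gene_symbol`, `mean_abs`, `mean_signed`.
#' @export
mean_abs_shap <- function(shap) {
  stopifnot(inherits(shap, "spore_shap"))
  tibble(gene_symbol = shap$gene_symbols,
         mean_abs = unname(colMeans(abs(shap$values))),
         mean_signed = unname(colMeans(shap$values))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs))
}

#' Dual-model positive-consensus genes
#'
#' Keeps only genes whose mean signed Shapley contribution toward the
#' Sporulating probability is strictly positive in *both* base models, and
#' ranks them by the average of the two models' mean absolute attributions.
#'
#' @param shap_rf,shap_svm `spore_shap` objects over the same gene order.
#' @return A `spore_consensus` tibble: `gene_symbol`, `mean_abs_rf`,
#'   `mean_abs_svm`, `score` (ranking key), in descending `score` order.
#' @export
consensus_positive_genes <- function(shap_rf, shap_svm) {
  if (!identical(shap_rf$gene_symbols, shap_svm$gene_symbols)) {
    stop("Gene order differs between the two attribution sets", call. = FALSE)
  }
  a <- mean_abs_shap(shap_rf) |>
    dplyr::rename(mean_abs_rf = "mean_abs", mean_signed_rf = "mean_signed")
  b <- mean_abs_shap(shap_svm) |>
    dplyr::rename(mean_abs_svm = "mean_abs", mean_signed_svm = "mean_signed")
  out <- dplyr::inner_join(a, b, by = "gene_symbol") |>
    dplyr::filter(.data$mean_signed_rf > 0, .data$mean_signed_svm > 0) |>
    dplyr::mutate(score = (.data$mean_abs_rf + .data$mean_abs_svm) / 2) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::select("gene_symbol", "mean_abs_rf", "mean_abs_svm", "score")
  attr(out, "rule_tag") <- "positive-mean-shap-in-both-models"
  class(out) <- c("spore_consensus", class(out))
  out
}

#' Core genes of a predicted group
#'
#' Genes present (value 1) in every listed genome — e.g. the universally
#' conserved genes across all genomes predicted as spore-formers.
#'
#' @param features Feature tibble.
#' @param genome_ids Genome ids defining the group (must be non-empty and a
#'   subset of the matrix rows).
#' @param catalog Optional catalog; when given, stage annotations are
#'   joined onto the result.
#' @return Tibble `gene_symbol` (plus `stage` when a catalog is supplied),
#'   in catalog/matrix column order.
#' @export
core_genes <- function(features, genome_ids, catalog = NULL) {
  counts <- gene_presence_counts(features, genome_ids)
  core <- counts[counts$n_present == length(unique(genome_ids)), "gene_symbol"]
  if (!is.null(catalog)) {
    core <- dplyr::left_join(
      core, as_tibble(catalog)[c("gene_symbol", "stage")],
      by = "gene_symbol")
  }
  core
}

#' Per-gene presence counts within a group
#'
#' How many of the listed genomes carry each gene — the input of the
#' presence-count histogram over predicted spore-formers.
#'
#' @inheritParams core_genes
#' @return Tibble `gene_symbol`, `n_present` in matrix column order.
#' @export
gene_presence_counts <- function(features, genome_ids) {
  if (length(genome_ids) == 0) {
    stop("`genome_ids` must be non-empty", call. = FALSE)
  }
  missing <- setdiff(genome_ids, features$genome_id)
  if (length(missing) > 0) {
    stop("Genome id(s) not in the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- feature_values(features[features$genome_id %in% genome_ids, ])
  tibble(gene_symbol = colnames(sub), n_present = as.integer(colSums(sub)))
}

#' Per-genome gene-content counts by sporulation stage
#'
#' Number of present catalog genes per genome within each stage category —
#' the input of stage-resolved gene-content profiles.
#'
#' @param features Feature tibble.
#' @param catalog A validated gene catalog.
#' @return Tibble `genome_id`, `stage`, `n_genes` (stage in
#'   [stage_categories()] order).
#' @export
stage_gene_counts <- function(features, catalog) {
  validate_catalog(catalog)
  aligned <- align_features(features, catalog)
  m <- feature_values(aligned)
  stage <- factor(catalog$stage, levels = stage_categories())
  counts <- t(rowsum(t(m), group = stage))
  tibble(genome_id = rep(rownames(counts), ncol(counts)),
         stage = factor(rep(colnames(counts), each = nrow(counts)),
                        levels = stage_categories()),
         n_genes = as.integer(as.vector(counts))) |>
    dplyr::arrange(.data$genome_id, .data$stage)
}
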