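#' Binary (Jaccard) distance between genomes
#'
#' Pairwise distance over presence/absence profiles:
#' `d(i, j)` = (positions where exactly one genome has the gene) /
#' (positions where at least one does). A pair of all-zero genomes has
#' distance 0 by convention.
#'
#' @param features Feature tibble.
#' @return A `dist` object labeled by genome id.
#' @export
binary_distance <- function(features) {
  check_binary_features(features)
  d <- stats::dist(feature_values(features), method = "binary")
  d[is.nan(d)] <- 0  # all-zero pairs: no informative positions
  d
}

#' PCA of presence/absence profiles
#'
#' Centered (unscaled) principal component analysis of the 0/1 matrix.
#' Component signs follow a fixed convention — the largest-magnitude
#' loading of each component is made positive — so scores are reproducible
#' across runs and row orders.
#'
#' @param features Feature tibble with at least two genomes.
#' @return A `spore_pca`: `scores` tibble (`genome_id`, optional
#'   `phenotype`, `PC1`, ...), `loadings` tibble, and `percent_variance`
#'   (sums to 100).
#' @export
pca_presence_absence <- function(features) {
  check_binary_features(features)
  m <- feature_values(features)
  if (nrow(m) < 2) stop("PCA needs at least two genomes", call. = FALSE)
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  scores <- dplyr::bind_cols(
    features[intersect(c("genome_id", "phenotype"), names(features))],
    as_tibble(fit$x))
  loadings <- dplyr::bind_cols(tibble(gene_symbol = rownames(fit$rotation)),
                               as_tibble(fit$rotation))
  structure(list(scores = scores, loadings = loadings,
                 percent_variance = pct),
            class = "spore_pca")
}

#' @export
print.spore_pca <- function(x, ...) {
  cat("<spore_pca> ", nrow(x$scores), " genomes; PC1 ",
      sprintf("%.2f%%", x$percent_variance[1]), ", PC2 ",
      if (length(x$percent_variance) > 1)
        sprintf("%.2f%%", x$percent_variance[2]) else "-", "\n", sep = "")
  invisible(x)
}

# One-way ANOVA F statistic (closed form, used inside permutation loops).
f_oneway <- function(x, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  n <- length(x)
  ns <- tabulate(g)
  means <- as.vector(rowsum(x, g)) / ns
  gm <- mean(x)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((x - means[as.integer(g)])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Multivariate dispersion around group centroids
#'
#' Embeds the distance matrix by principal coordinates analysis
#' (double-centering of squared distances), computes each group's centroid
#' in that space, and measures every genome's distance to its group
#' centroid, combining real and imaginary axes as
#' `d^2 = d^2(positive-eigenvalue axes) - d^2(negative-eigenvalue axes)`
#' (floored at zero before the square root) — the standard treatment for
#' semi-metric distances. The group-difference statistic is the one-way
#' ANOVA F on the distances; use [permutation_anova()] for its p-value.
#'
#' @param dist A `dist` or symmetric matrix of pairwise distances.
#' @param groups Grouping vector (each group needs at least 2 members).
#' @return A `spore_dispersion`: `distances` tibble (`genome_id`, `group`,
#'   `distance`), `group_means`, `f_statistic`, and `p_value`/`
#'   n_permutations` (NA until [permutation_anova()] runs).
#' @export
betadispersion <- function(dist, groups) {
  D <- as.matrix(dist)
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) {
    stop("`groups` length must match the distance matrix", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("Every group needs at least 2 members", call. = FALSE)
  }
  ids <- rownames(D) %||% as.character(seq_len(n))
  # PCoA via double-centering of -D^2/2
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  neg <- eig$values < -tol
  coord <- function(keep) {
    if (!any(keep)) return(matrix(0, n, 0))
    sweep(eig$vectors[, keep, drop = FALSE], 2,
          sqrt(abs(eig$values[keep])), `*`)
  }
  P <- coord(pos)
  N <- coord(neg)
  dist_to_centroid <- numeric(n)
  for (lev in levels(groups)) {
    in_g <- groups == lev
    cp <- colMeans(P[in_g, , drop = FALSE])
    cn <- colMeans(N[in_g, , drop = FALSE])
    d2 <- rowSums(sweep(P[in_g, , drop = FALSE], 2, cp)^2) -
      rowSums(sweep(N[in_g, , drop = FALSE], 2, cn)^2)
    dist_to_centroid[in_g] <- sqrt(pmax(d2, 0))
  }
  distances <- tibble(genome_id = ids, group = groups,
                      distance = dist_to_centroid)
  group_means <- distances |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_distance = mean(.data$distance), .groups = "drop")
  structure(list(distances = distances, group_means = group_means,
                 f_statistic = f_oneway(dist_to_centroid, groups),
                 p_value = NA_real_, n_permutations = NA_integer_),
            class = "spore_dispersion")
}

#' Permutation ANOVA on dispersion distances
#'
#' Permutes the group labels over the fixed distance-to-centroid vector and
#' recomputes the F statistic each time;
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param dispersion A `spore_dispersion` from [betadispersion()].
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return The `spore_dispersion` with `p_value`, `n_permutations`, and the
#'   permuted statistics (`f_permuted`) filled in.
#' @export
permutation_anova <- function(dispersion, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(dispersion, "spore_dispersion"), n_permutations >= 1)
  x <- dispersion$distances$distance
  g <- dispersion$distances$group
  f_obs <- dispersion$f_statistic
  withr::local_seed(seed)
  f_perm <- vapply(seq_len(n_permutations),
                   function(i) f_oneway(x, sample(g)), double(1))
  dispersion$p_value <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  dispersion$n_permutations <- as.integer(n_permutations)
  dispersion$f_permuted <- f_perm
  dispersion
}

#' @export
print.spore_dispersion <- function(x, ...) {
  cat("<spore_dispersion> F=", signif(x$f_statistic, 4), sep = "")
  if (!is.na(x$p_value)) {
    cat(", p=", signif(x$p_value, 4), " (", x$n_permutations,
        " permutations)", sep = "")
  }
  cat("\n")
  print(x$group_means)
  invisible(x)
}
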