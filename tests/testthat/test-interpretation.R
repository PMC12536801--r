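make_feature_tibble <- function(M, prefix = "g") {
  colnames(M) <- paste0("gene", seq_len(ncol(M)))
  dplyr::bind_cols(
    tibble::tibble(genome_id = sprintf("%s%02d", prefix, seq_len(nrow(M)))),
    tibble::as_tibble(M))
}

test_that("a constant model attributes (approximately) nothing", {
  set.seed(31)
  X <- make_feature_tibble(matrix(rbinom(5 * 6, 1, 0.5), 5, 6))
  B <- make_feature_tibble(matrix(rbinom(10 * 6, 1, 0.5), 10, 6), "b")
  s <- shap_values(function(M) rep(0.42, nrow(M)), X, B, n_samples = 30,
                   seed = 1, model_tag = "const")
  expect_true(all(abs(s$values) < 1e-12))
  expect_equal(s$base_value, 0.42)
})

test_that("additive model attributions match the closed form and oracle", {
  # p = 0.1 + 0.4*x1 + 0.2*x2 over an independent background
  f <- function(M) 0.1 + 0.4 * M[, 1] + 0.2 * M[, 2]
  set.seed(32)
  B <- matrix(rbinom(40 * 4, 1, 0.5), 40, 4)
  Bt <- make_feature_tibble(B, "b")
  x <- c(1, 1, 0, 1)
  Xt <- make_feature_tibble(matrix(x, 1), "x")
  s <- shap_values(f, Xt, Bt, n_samples = 400, seed = 2)
  # additive model: phi_j = w_j * (x_j - mean background x_j), exactly
  expect_equal(unname(s$values[1, 1]), 0.4 * (1 - mean(B[, 1])),
               tolerance = 1e-10)
  expect_equal(unname(s$values[1, 2]), 0.2 * (1 - mean(B[, 2])),
               tolerance = 1e-10)
  expect_equal(unname(s$values[1, 3:4]), c(0, 0), tolerance = 1e-10)
  oracle <- exact_shap_oracle(f, x, B)
  expect_equal(unname(s$values[1, ]), oracle, tolerance = 1e-8)
})

test_that("symmetric features receive equal attributions", {
  # two features with identical role and identical background marginals
  f <- function(M) plogis(1.5 * M[, 1] + 1.5 * M[, 2] - 1)
  B <- make_feature_tibble(cbind(rep(0:1, each = 8), rep(0:1, times = 8),
                                 rbinom(16, 1, 0.5)), "b")
  Xt <- make_feature_tibble(matrix(c(1, 1, 0), 1), "x")
  s <- shap_values(f, Xt, B, n_samples = 2000, seed = 3)
  expect_equal(unname(s$values[1, 1]), unname(s$values[1, 2]),
               tolerance = 0.02)
})

test_that("per-gene summaries and the consensus rule behave as specified", {
  mk_shap <- function(values, tag) {
    structure(list(values = values, base_value = 0, n_samples = 10,
                   model_tag = tag,
                   genome_ids = rownames(values),
                   gene_symbols = colnames(values)),
              class = "spore_shap")
  }
  v <- matrix(c(0.1, 0.3, -0.3, -0.1), 2, 2,
              dimnames = list(c("a", "b"), c("gX", "gY")))
  m <- mean_abs_shap(mk_shap(v, "rf"))
  expect_equal(m$mean_abs, c(0.2, 0.2))
  expect_equal(m$mean_signed[m$gene_symbol == "gX"], 0.2)
  expect_equal(m$mean_signed[m$gene_symbol == "gY"], -0.2)

  zero <- mean_abs_shap(mk_shap(v * 0, "rf"))
  expect_true(all(zero$mean_abs == 0))

  # gX positive in both, gY positive only in svm -> only gX kept
  rf <- mk_shap(v, "rf")
  svm <- mk_shap(abs(v), "svm_rbf")
  cons <- consensus_positive_genes(rf, svm)
  expect_equal(cons$gene_symbol, "gX")
  expect_equal(cons$score, (0.2 + 0.2) / 2)

  # disjoint positive sets -> empty
  cons0 <- consensus_positive_genes(rf, mk_shap(-abs(v), "svm_rbf"))
  expect_equal(nrow(cons0), 0)

  reordered <- mk_shap(v[, 2:1], "svm_rbf")
  expect_error(consensus_positive_genes(rf, reordered), "order differs")
})

test_that("core genes are exactly those present in every listed genome", {
  features <- tibble::tibble(
    genome_id = c("g1", "g2", "g3"),
    geneA = c(1L, 1L, 1L), geneB = c(1L, 0L, 1L), geneC = c(0L, 0L, 0L))
  core <- core_genes(features, c("g1", "g2", "g3"))
  expect_equal(core$gene_symbol, "geneA")
  counts <- gene_presence_counts(features, c("g1", "g2", "g3"))
  expect_equal(counts$n_present, c(3L, 2L, 0L))

  single <- core_genes(features, "g1")
  expect_equal(single$gene_symbol, c("geneA", "geneB"))

  expect_error(core_genes(features, character(0)), "non-empty")
  expect_error(core_genes(features, "nope"), "not in the matrix")
})

test_that("stage-resolved gene counts sum to the genome totals", {
  cat6 <- read_gene_catalog(write_tiny_catalog())
  sim <- simulate_genomes(simulation_config(n_sporulating = 3,
                                            n_nonsporulating = 3,
                                            n_informative = 2, seed = 5),
                          catalog = cat6)
  counts <- stage_gene_counts(sim, cat6)
  totals <- counts |>
    dplyr::summarise(n = sum(n_genes), .by = genome_id) |>
    dplyr::arrange(genome_id)
  expected <- sort(rowSums(feature_values(sim)))
  expect_equal(totals$n[order(totals$genome_id)],
               as.integer(rowSums(feature_values(sim))[order(sim$genome_id)]))
})
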