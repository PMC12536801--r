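test_that("default simulation matches the study-scale cohort design", {
  sim <- standard_sim()
  expect_equal(nrow(sim), 136)
  expect_equal(length(feature_gene_names(sim)), 160)
  expect_equal(unname(as.vector(table(sim$phenotype))), c(68, 68))
  expect_length(attr(sim, "planted_genes"), 20)
  expect_true(all(feature_values(sim) %in% c(0, 1)))
})

test_that("extreme class probabilities without dropout plant an indicator", {
  cfg <- simulation_config(n_sporulating = 10, n_nonsporulating = 10,
                           n_informative = 5,
                           p_present_informative = c(1, 0), dropout = 0,
                           seed = 2)
  sim <- simulate_genomes(cfg)
  planted <- attr(sim, "planted_genes")
  for (g in planted) {
    expect_equal(sim[[g]], as.integer(sim$phenotype == "Sporulating"))
  }
})

test_that("noise genes hit their presence frequency within binomial error", {
  cfg <- simulation_config(seed = 7)
  sim <- simulate_genomes(cfg)
  noise <- setdiff(feature_gene_names(sim), attr(sim, "planted_genes"))
  # dropout only touches sporulating rows; check the untouched class
  nonspor <- feature_values(sim[sim$phenotype == "Non-Sporulating", ])
  freq <- colMeans(nonspor[, noise])
  se <- sqrt(0.2 * 0.8 / nrow(nonspor))
  expect_true(all(abs(freq - 0.2) <= 3.5 * se))
  expect_lt(abs(mean(freq) - 0.2), 3 * se / sqrt(length(noise)) * 5)
})

test_that("stage blocks induce the configured within-block correlation", {
  cfg <- simulation_config(n_sporulating = 600, n_nonsporulating = 2,
                           n_informative = 32,
                           p_present_informative = c(0.5, 0.5),
                           dropout = 0, stage_block_correlation = 0.4,
                           seed = 8)
  sim <- simulate_genomes(cfg)
  planted <- attr(sim, "planted_genes")
  cat160 <- default_gene_catalog()
  stages <- cat160$stage[match(planted, cat160$gene_symbol)]
  expect_gt(length(unique(stages)), 1)  # informative genes span >1 block
  m <- feature_values(sim[sim$phenotype == "Sporulating", ])[, planted]
  within <- c(); between <- c()
  for (i in seq_along(planted)[-length(planted)]) {
    for (j in (i + 1):length(planted)) {
      r <- cor(m[, i], m[, j])
      if (stages[i] == stages[j]) within <- c(within, r)
      else between <- c(between, r)
    }
  }
  expect_equal(mean(within), 0.4, tolerance = 0.1)
  expect_lt(abs(mean(between)), 0.1)
})

test_that("dropout only removes genes, and only from sporulating genomes", {
  cfg0 <- simulation_config(seed = 9, dropout = 0)
  cfg5 <- simulation_config(seed = 9, dropout = 0.5)
  m0 <- feature_values(simulate_genomes(cfg0))
  m5 <- feature_values(simulate_genomes(cfg5))
  spor <- grepl("^spor_", rownames(m0))
  expect_true(all(m5[spor, ] <= m0[spor, ]))          # 1 -> 0 only
  expect_identical(m5[!spor, ], m0[!spor, ])          # others untouched
  expect_lt(sum(m5[spor, ]), sum(m0[spor, ]))
})

test_that("simulation is deterministic and seed-sensitive", {
  a <- simulate_genomes(small_sim_config())
  b <- simulate_genomes(small_sim_config())
  expect_identical(feature_values(a), feature_values(b))
  c2 <- simulate_genomes(small_sim_config(seed = 43))
  expect_false(identical(feature_values(a), feature_values(c2)))
  expect_error(
    simulate_genomes(simulation_config(n_informative = 999)), "exceeds")
})

test_that("non-Firmicutes simulation yields near-zero gene content", {
  nf0 <- simulate_nonfirmicutes(20, p_stray = 0, seed = 1)
  expect_true(all(feature_values(nf0) == 0))
  expect_false("phenotype" %in% names(nf0))

  nf <- simulate_nonfirmicutes(496, p_stray = 0.01, seed = 2)
  expect_equal(nrow(nf), 496)
  mean_count <- mean(rowSums(feature_values(nf)))
  se <- sqrt(160 * 0.01 * 0.99 / 496)
  expect_lt(abs(mean_count - 1.6), 3 * se)
})

test_that("synthetic annotations round-trip to the exact input matrix", {
  cat160 <- default_gene_catalog()
  sim <- simulate_genomes(small_sim_config(seed = 11))
  dir <- withr::local_tempdir()
  simulate_annotations(sim, cat160, dir, seed = 11)
  rebuilt <- suppressMessages(
    build_feature_matrix(dir, cat160,
                         labels = tibble::tibble(
                           genome_id = sim$genome_id,
                           phenotype = as.character(sim$phenotype))))
  rebuilt <- rebuilt[match(sim$genome_id, rebuilt$genome_id), ]
  expect_identical(feature_values(rebuilt), feature_values(sim))
  expect_equal(as.character(rebuilt$phenotype), as.character(sim$phenotype))

  # the KO-only emission path is exercised: some rows carry no gene name
  one <- readLines(list.files(dir, full.names = TRUE)[1])
  body <- one[!startsWith(one, "#")]
  names_col <- vapply(strsplit(body, "\t"), `[`, character(1), 3)
  expect_true(any(names_col == "-"))

  # an all-zero genome still writes a parseable decoy-only file
  zero <- sim[1, ]
  zero[feature_gene_names(zero)] <- 0L
  zero$genome_id <- "zero_genome"
  dir2 <- withr::local_tempdir()
  simulate_annotations(zero, cat160, dir2, seed = 1)
  rec <- read_emapper(file.path(dir2, "zero_genome.emapper.annotations"))
  expect_gt(nrow(rec), 0)
  expect_equal(sum(encode_genome(rec, cat160)), 0)
})

test_that("a wider informative gap monotonically improves held-out AUC", {
  gap_auc <- function(p_hi) {
    med <- vapply(1:3, function(s) {
      cfg <- simulation_config(n_sporulating = 30, n_nonsporulating = 30,
                               n_informative = 10,
                               p_present_informative = c(p_hi, 0.2),
                               dropout = 0.05, seed = 500 + s)
      sim <- simulate_genomes(cfg)
      part <- stratified_partition(sim, 0.7, seed = s)
      tr <- sim[sim$genome_id %in% part$train, ]
      te <- sim[sim$genome_id %in% part$test, ]
      rf <- tune_random_forest(tr, fast_cv(s))
      roc_auc(predict(rf, te), te$phenotype)
    }, double(1))
    stats::median(med)
  }
  aucs <- vapply(c(0.2, 0.5, 0.9), gap_auc, double(1))
  expect_true(all(diff(aucs) >= -0.02))  # monotone up to small jitter
  expect_gt(aucs[3], aucs[1])
})
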