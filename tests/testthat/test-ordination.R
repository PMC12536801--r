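test_that("binary distance equals the closed-form Jaccard distance", {
  f <- tibble::tibble(genome_id = c("a", "b"),
                      g1 = c(1L, 1L), g2 = c(0L, 1L), g3 = c(1L, 0L))
  expect_equal(as.vector(binary_distance(f)), 2 / 3)

  same <- tibble::tibble(genome_id = c("a", "b"), g1 = c(1L, 1L),
                         g2 = c(0L, 0L))
  expect_equal(as.vector(binary_distance(same)), 0)

  zeros <- tibble::tibble(genome_id = c("a", "b", "c"),
                          g1 = c(0L, 0L, 1L), g2 = c(0L, 0L, 0L))
  d <- as.matrix(binary_distance(zeros))
  expect_equal(d["a", "b"], 0)  # all-zero pair: 0 by convention
  expect_equal(d["a", "c"], 1)

  # exhaustive check on random 10x12 matrices against the brute-force counter
  for (s in 1:5) {
    set.seed(400 + s)
    m <- matrix(rbinom(10 * 12, 1, 0.4), 10, 12)
    ft <- dplyr::bind_cols(tibble::tibble(genome_id = sprintf("g%02d", 1:10)),
                           tibble::as_tibble(`colnames<-`(
                             m, paste0("gene", 1:12))))
    got <- as.matrix(binary_distance(ft))
    for (i in 1:9) {
      for (j in (i + 1):10) {
        expect_equal(got[i, j], jaccard_oracle(m[i, ], m[j, ]))
      }
    }
  }
})

test_that("presence/absence PCA is centered, complete, and sign-fixed", {
  sim <- small_sim()
  pca <- pca_presence_absence(sim)
  expect_equal(sum(pca$percent_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(pca$percent_variance) < 1e-9))

  # constant columns get zero loadings
  const_gene <- feature_gene_names(sim)[
    vapply(sim[feature_gene_names(sim)],
           function(x) length(unique(x)) == 1, logical(1))]
  if (length(const_gene) > 0) {
    loads <- as.matrix(pca$loadings[
      pca$loadings$gene_symbol %in% const_gene, -1])
    expect_true(all(abs(loads) < 1e-12))
  }

  # row-order invariance up to the fixed sign convention
  withr::with_seed(41, shuffled <- sim[sample(nrow(sim)), ])
  pca2 <- pca_presence_absence(shuffled)
  ord <- match(pca$scores$genome_id, pca2$scores$genome_id)
  expect_equal(pca2$scores$PC1[ord], pca$scores$PC1, tolerance = 1e-8)
  expect_equal(pca2$scores$PC2[ord], pca$scores$PC2, tolerance = 1e-8)

  two <- sim[1:2, ]
  pca_two <- pca_presence_absence(two)
  expect_equal(pca_two$percent_variance[1], 100, tolerance = 1e-9)
  expect_error(pca_presence_absence(sim[1, ]), "at least two")
})

test_that("dispersion distances equal direct centroid geometry (Euclidean)", {
  # 6 points in the plane, 2 groups; PCoA of Euclidean distances must
  # reproduce plain centroid distances
  pts <- rbind(c(0, 0), c(2, 0), c(1, 2), c(5, 5), c(7, 5), c(6, 7))
  rownames(pts) <- sprintf("p%d", 1:6)
  groups <- rep(c("A", "B"), each = 3)
  d <- stats::dist(pts)
  disp <- betadispersion(d, groups)
  direct <- unlist(lapply(c(1, 4), function(start) {
    block <- pts[start:(start + 2), ]
    cen <- colMeans(block)
    sqrt(rowSums(sweep(block, 2, cen)^2))
  }))
  expect_equal(disp$distances$distance, unname(direct), tolerance = 1e-9)
  expect_equal(disp$f_statistic,
               summary(stats::aov(disp$distances$distance ~ groups))[[1]][
                 "groups", "F value"], tolerance = 1e-9)

  # identical point clouds in both groups: equal dispersion, F ~ 0
  dup <- rbind(pts[1:3, ], pts[1:3, ] + 100)
  rownames(dup) <- sprintf("q%d", 1:6)
  disp2 <- betadispersion(stats::dist(dup), groups)
  expect_equal(disp2$group_means$mean_distance[1],
               disp2$group_means$mean_distance[2], tolerance = 1e-9)
  expect_lt(disp2$f_statistic, 1e-12)

  # all points identical: zero distances
  flat <- matrix(1, 4, 2, dimnames = list(sprintf("r%d", 1:4), NULL))
  disp3 <- betadispersion(stats::dist(flat), rep(c("A", "B"), 2))
  expect_true(all(disp3$distances$distance == 0))

  expect_error(betadispersion(d, c("A", "A", "A", "A", "A", "B")),
               "at least 2 members")
})

test_that("dispersion agrees with the vegan reference on binary profiles", {
  skip_if_not_installed("vegan")
  sim <- small_sim()
  d <- binary_distance(sim)
  disp <- betadispersion(d, sim$phenotype)
  ref <- vegan::betadisper(d, sim$phenotype, type = "centroid")
  expect_equal(disp$distances$distance, unname(ref$distances),
               tolerance = 1e-8)
  ref_f <- stats::anova(ref)[["F value"]][1]
  expect_equal(disp$f_statistic, ref_f, tolerance = 1e-8)
})

test_that("permutation p-value follows its defining formula and null", {
  pts <- matrix(rnorm(16 * 3), 16, 3,
                dimnames = list(sprintf("s%02d", 1:16), NULL))
  groups <- rep(c("A", "B"), each = 8)
  disp <- betadispersion(stats::dist(pts), groups)
  res <- permutation_anova(disp, n_permutations = 99, seed = 5)
  expect_equal(res$p_value,
               (1 + sum(res$f_permuted >= res$f_statistic)) / 100)
  expect_equal(res$n_permutations, 99)

  # identical groups: p near 1
  dup <- rbind(pts[1:8, ], pts[1:8, ])
  rownames(dup) <- sprintf("t%02d", 1:16)
  disp_dup <- permutation_anova(
    betadispersion(stats::dist(dup), groups), 199, seed = 6)
  expect_gt(disp_dup$p_value, 0.5)

  # F statistic invariant to swapping group labels
  swapped <- betadispersion(stats::dist(pts),
                            rep(c("B", "A"), each = 8))
  expect_equal(swapped$f_statistic, disp$f_statistic, tolerance = 1e-12)
})
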