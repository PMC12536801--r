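write_annotation <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("## some emapper-style preamble",
               "#query\tevalue\tPreferred_name\tKEGG_ko", lines), path)
  path
}

test_that("annotation parser splits KO tokens and honors e-value filter", {
  path <- write_annotation(c(
    "orf1\t1e-50\tspoVD\tko:K08384",
    "orf2\t1e-3\tgerA\tko:K06295,ko:K06296",
    "orf3\t2e-10\t-\t-"))
  rec <- read_emapper(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$ko_ids[2], "K06295,K06296")
  expect_true(is.na(rec$preferred_name[3]))
  expect_equal(rec$ko_ids[3], "")

  filtered <- read_emapper(path, max_evalue = 1e-5)
  expect_equal(filtered$query, c("orf1", "orf3"))
})

test_that("comment-only files parse to empty; bad headers are schema errors", {
  empty <- write_annotation(character(0))
  expect_equal(nrow(read_emapper(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("#query\tevalue\tsomething_else", "orf1\t1e-9\tx"), bad)
  expect_error(read_emapper(bad), "schema error.*something_else")

  no_header <- tempfile(fileext = ".tsv")
  writeLines("orf1\t1e-9\tspoVD\tko:K08384", no_header)
  expect_error(read_emapper(no_header), "no '#query' header")

  expect_error(read_emapper(tempfile()), "not found")
})

test_that("encoding matches by name (case/alias) and by KO, presence-only", {
  cat6 <- read_gene_catalog(write_tiny_catalog())
  rec <- read_emapper(write_annotation(c(
    "orf1\t1e-50\tSPOVD\t-",          # case-insensitive name match
    "orf2\t1e-50\tgerAA\t-",          # alias match -> gerA
    "orf3\t1e-50\t-\tko:K01448",      # KO-only match -> sleB
    "orf4\t1e-50\tunknownX\tko:K99999",  # no match
    "orf5\t1e-50\tSPOVD\t-")))        # duplicate hit, multiplicity ignored
  v <- encode_genome(rec, cat6)
  expect_equal(v, c(spoVD = 1L, spo0A = 0L, gerA = 1L, cotX = 0L,
                    sleB = 1L, ftsW = 0L))

  expect_equal(sum(encode_genome(rec[0, ], cat6)), 0)

  # idempotent under record duplication
  expect_equal(encode_genome(rec[rep(1:5, 3), ], cat6), v)

  # monotone: removing records never turns a 0 into a 1
  v_less <- encode_genome(rec[-3, ], cat6)
  expect_true(all(v_less <= v))
})

test_that("build_feature_matrix encodes a directory deterministically", {
  cat6 <- read_gene_catalog(write_tiny_catalog())
  dir <- withr::local_tempdir()
  writeLines(c("#query\tevalue\tPreferred_name\tKEGG_ko",
               "orf1\t1e-50\tspoVD\tko:K08384"),
             file.path(dir, "gB.emapper.annotations"))
  writeLines(c("#query\tevalue\tPreferred_name\tKEGG_ko"),
             file.path(dir, "gA.tsv"))
  labels <- tibble::tibble(genome_id = c("gA", "gB", "ghost"),
                           phenotype = c("Non-Sporulating", "Sporulating",
                                         "Sporulating"))
  expect_warning(
    suppressMessages(m <- build_feature_matrix(dir, cat6, labels = labels)),
    "ghost")
  expect_equal(m$genome_id, c("gA", "gB"))  # sorted for determinism
  expect_equal(sum(feature_values(m)["gA", ]), 0)  # empty file -> all-zero
  expect_equal(as.vector(feature_values(m)["gB", "spoVD"]), 1)
  expect_equal(as.character(m$phenotype), c("Non-Sporulating", "Sporulating"))

  m2 <- suppressMessages(suppressWarnings(
    build_feature_matrix(dir, cat6, labels = labels)))
  expect_identical(m[], m2[])
})

test_that("alignment restores catalog order, zero-fills, drops, and guards", {
  cat6 <- read_gene_catalog(write_tiny_catalog())
  sim <- simulate_genomes(simulation_config(n_sporulating = 4,
                                            n_nonsporulating = 4,
                                            n_informative = 3, seed = 3),
                          catalog = cat6)
  genes <- feature_gene_names(sim)

  permuted <- sim[c("genome_id", "phenotype", rev(genes))]
  aligned <- align_features(permuted, cat6)
  expect_identical(aligned[], sim[])

  dropped <- sim[c("genome_id", "phenotype", genes[-2])]
  expect_warning(back <- align_features(dropped, cat6), "Zero-filling")
  expect_true(all(back[[genes[2]]] == 0))

  extra <- dplyr::mutate(sim, not_a_gene = 1L)
  expect_warning(cleaned <- align_features(extra, cat6), "Dropping")
  expect_false("not_a_gene" %in% names(cleaned))

  tiny <- sim[c("genome_id", "phenotype", genes[1:2])]
  expect_error(align_features(tiny, cat6), "does not look like")
})

test_that("feature matrix CSV and labels TSV round-trip", {
  sim <- small_sim()
  f <- tempfile(fileext = ".csv")
  l <- tempfile(fileext = ".tsv")
  write_feature_matrix(sim, f)
  write_labels(sim, l)
  back <- read_feature_matrix(f, labels = read_labels(l))
  expect_equal(back$genome_id, sim$genome_id)
  expect_identical(feature_values(back), feature_values(sim))
  expect_equal(as.character(back$phenotype), as.character(sim$phenotype))
})
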