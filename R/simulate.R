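#' Simulation settings for the synthetic labeled cohort
#'
#' Defaults emulate the study conditions the classifier assumes: a balanced
#' cohort of 68 sporulating and 68 non-sporulating genomes over a 160-gene
#' catalog; 20 informative genes present with probability 0.9 in
#' spore-formers and 0.1 in non-spore-formers; the remaining genes are
#' uninformative noise at presence probability 0.2; genome-incompleteness
#' dropout flips 5% of spore-formers' present genes to absent (assembly
#' loses genes, never invents them); informative genes co-occur within
#' sporulation-stage blocks with pairwise correlation ~0.3, mimicking
#' regulon structure.
#'
#' @param n_sporulating,n_nonsporulating Class sizes (defaults 68/68).
#' @param n_informative Number of class-informative genes (default 20).
#' @param p_present_informative Length-2 presence probabilities of
#'   informative genes in (sporulating, non-sporulating) genomes
#'   (default `c(0.9, 0.1)`).
#' @param p_present_noise Presence probability of uninformative genes
#'   (default 0.2).
#' @param dropout Probability a present gene of a sporulating genome is
#'   dropped (default 0.05).
#' @param stage_block_correlation Target pairwise presence correlation of
#'   informative genes within a stage block (default 0.3).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_sporulating = 68, n_nonsporulating = 68,
                              n_informative = 20,
                              p_present_informative = c(0.9, 0.1),
                              p_present_noise = 0.2, dropout = 0.05,
                              stage_block_correlation = 0.3, seed = 1) {
  probs <- c(p_present_informative, p_present_noise, dropout,
             stage_block_correlation)
  stopifnot(length(p_present_informative) == 2,
            all(probs >= 0), all(probs <= 1),
            dropout < 1, stage_block_correlation < 1,
            n_sporulating >= 1, n_nonsporulating >= 1, n_informative >= 1)
  structure(list(n_sporulating = as.integer(n_sporulating),
                 n_nonsporulating = as.integer(n_nonsporulating),
                 n_informative = as.integer(n_informative),
                 p_present_informative = p_present_informative,
                 p_present_noise = p_present_noise, dropout = dropout,
                 stage_block_correlation = stage_block_correlation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a labeled presence/absence cohort
#'
#' Generates a feature matrix with planted class signal. Informative genes
#' are taken block-wise from the catalog's stage categories (stages in
#' catalog order until the quota is filled), so they share stage blocks;
#' within a block each genome draws a latent Bernoulli at the
#' class-conditional presence probability and each gene copies it with
#' probability `sqrt(stage_block_correlation)` (independent redraw
#' otherwise), giving pairwise within-block correlation of approximately
#' `stage_block_correlation` while preserving the marginal presence
#' probability. Noise genes are independent Bernoulli draws. Dropout then
#' flips present genes of sporulating genomes to absent. Fully
#' deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param catalog Gene catalog (default [default_gene_catalog()]).
#' @return Labeled feature tibble with attributes `planted_genes` (the
#'   informative gene symbols) and `sim_config`.
#' @export
#' @examples
#' sim <- simulate_genomes(simulation_config(seed = 7))
#' dim(sim)  # 136 x 162 (genome_id, phenotype, 160 genes)
simulate_genomes <- function(config = simulation_config(),
                             catalog = default_gene_catalog()) {
  validate_catalog(catalog)
  d <- nrow(catalog)
  if (config$n_informative > d) {
    stop("n_informative exceeds the catalog size", call. = FALSE)
  }
  withr::local_seed(config$seed)

  # block fill: stages in catalog order of first appearance until quota
  stage_first <- catalog$stage[!duplicated(catalog$stage)]
  informative <- character(0)
  for (st in stage_first) {
    need <- config$n_informative - length(informative)
    if (need <= 0) break
    pool <- catalog$gene_symbol[catalog$stage == st]
    informative <- c(informative, utils::head(pool, need))
  }
  blocks <- catalog$stage[match(informative, catalog$gene_symbol)]

  n_s <- config$n_sporulating
  n_n <- config$n_nonsporulating
  ids <- c(sprintf("spor_%03d", seq_len(n_s)),
           sprintf("nonspor_%03d", seq_len(n_n)))
  phen <- c(rep(positive_class, n_s), rep(phenotype_levels[1], n_n))
  copy_p <- sqrt(config$stage_block_correlation)

  m <- matrix(0L, n_s + n_n, d,
              dimnames = list(ids, catalog$gene_symbol))
  for (cls in 1:2) {
    rows <- if (cls == 1) seq_len(n_s) else n_s + seq_len(n_n)
    p_inf <- config$p_present_informative[cls]
    for (b in unique(blocks)) {
      genes <- informative[blocks == b]
      z <- stats::rbinom(length(rows), 1, p_inf)
      for (g in genes) {
        copy <- stats::rbinom(length(rows), 1, copy_p) == 1
        fresh <- stats::rbinom(length(rows), 1, p_inf)
        m[rows, g] <- ifelse(copy, z, fresh)
      }
    }
  }
  noise_genes <- setdiff(catalog$gene_symbol, informative)
  m[, noise_genes] <- stats::rbinom(length(m[, noise_genes]), 1,
                                    config$p_present_noise)
  if (config$dropout > 0 && n_s > 0) {
    spor_rows <- seq_len(n_s)
    ones <- which(m[spor_rows, , drop = FALSE] == 1L)
    drop <- ones[stats::rbinom(length(ones), 1, config$dropout) == 1]
    sub <- m[spor_rows, , drop = FALSE]
    sub[drop] <- 0L
    m[spor_rows, ] <- sub
  }
  features <- dplyr::bind_cols(
    tibble(genome_id = ids, phenotype = as_phenotype(phen)),
    as_tibble(m))
  attr(features, "planted_genes") <- informative
  attr(features, "sim_config") <- config
  features
}

#' Simulate genomes outside the spore-forming phylum
#'
#' Near-zero sporulation-gene content: every gene is an independent
#' Bernoulli draw at a small stray-annotation probability. Used for
#' specificity testing — a trained classifier should assign these genomes
#' low sporulation probability.
#'
#' @param n Number of genomes.
#' @param p_stray Per-gene stray presence probability (default 0.01).
#' @param seed Integer seed.
#' @param catalog Gene catalog fixing the feature space.
#' @return Unlabeled feature tibble.
#' @export
simulate_nonfirmicutes <- function(n, p_stray = 0.01, seed = 1,
                                   catalog = default_gene_catalog()) {
  stopifnot(n >= 1, p_stray >= 0, p_stray <= 1)
  withr::local_seed(seed)
  d <- nrow(catalog)
  m <- matrix(stats::rbinom(n * d, 1, p_stray), n, d,
              dimnames = list(sprintf("nonfirm_%03d", seq_len(n)),
                              catalog$gene_symbol))
  dplyr::bind_cols(tibble(genome_id = rownames(m)), as_tibble(m))
}

#' Write synthetic annotation files for a feature matrix
#'
#' Emits one eggNOG-mapper style TSV per genome such that parsing and
#' re-encoding reproduces the input matrix exactly. Every present gene
#' yields one row carrying the gene either via `Preferred_name` (optionally
#' also its KO) or, with probability 0.5, via the KO column only (testing
#' the KO matching path); genes without a KO always use the name path.
#' Decoy rows with non-catalog names and KOs are appended to every file.
#'
#' @param features Feature tibble aligned to `catalog`.
#' @param catalog A validated gene catalog.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the written file paths, invisibly.
#' @export
simulate_annotations <- function(features, catalog, out_dir, seed = 1) {
  validate_catalog(catalog)
  check_binary_features(features)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(seed)
  decoy_names <- setdiff(c("dnaA", "rpoB", "gyrB", "recA", "rpsL"),
                         tolower(catalog$gene_symbol))
  catalog_kos <- unlist(lapply(catalog$ko_ids, split_tokens))
  decoy_kos <- setdiff(sprintf("K%05d", 101:120), catalog_kos)
  m <- feature_values(features)
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    id <- rownames(m)[i]
    present <- colnames(m)[m[i, ] == 1]
    rows <- character(0)
    orf <- 0L
    for (g in present) {
      orf <- orf + 1L
      entry <- catalog[catalog$gene_symbol == g, ]
      kos <- split_tokens(entry$ko_ids)
      ko_cell <- if (length(kos) > 0) {
        paste(paste0("ko:", kos), collapse = ",")
      } else "-"
      ko_only <- length(kos) > 0 && stats::runif(1) < 0.5
      name_cell <- if (ko_only) "-" else g
      rows <- c(rows, paste(sprintf("%s_orf%04d", id, orf),
                            format(10^(-stats::runif(1, 20, 80)),
                                   digits = 3, scientific = TRUE),
                            name_cell, ko_cell, sep = "\t"))
    }
    n_decoy <- 3L
    for (j in seq_len(n_decoy)) {
      orf <- orf + 1L
      rows <- c(rows, paste(sprintf("%s_orf%04d", id, orf),
                            format(10^(-stats::runif(1, 20, 80)),
                                   digits = 3, scientific = TRUE),
                            sample(decoy_names, 1),
                            paste0("ko:", sample(decoy_kos, 1)),
                            sep = "\t"))
    }
    path <- file.path(out_dir, paste0(id, ".emapper.annotations"))
    writeLines(c("## synthetic annotation file",
                 "#query\tevalue\tPreferred_name\tKEGG_ko", rows), path)
    paths[i] <- path
  }
  invisible(paths)
}
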