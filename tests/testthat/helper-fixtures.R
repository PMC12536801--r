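# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A tiny hand-written catalog over 6 genes / 3 stages.
tiny_catalog <- function() {
  tibble::tibble(
    gene_symbol = c("spoVD", "spo0A", "gerA", "cotX", "sleB", "ftsW"),
    ko_ids = c("K08384", "K07699", "K06295,K06296", "", "K01448", "K03588"),
    aliases = c("SpoVD_pbp", "", "gerAA", "", "", ""),
    stage = c("spore cortex", "Spo0A regulon", "germination", "spore coat",
              "germination", "spore cortex"))
}

write_tiny_catalog <- function(path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tiny_catalog(), path)
  path
}

# Small fast simulated cohort for unit tests (not the study-scale defaults).
small_sim_config <- function(seed = 42, ...) {
  simulation_config(n_sporulating = 24, n_nonsporulating = 24,
                    n_informative = 12, seed = seed, ...)
}

small_sim <- function() {
  cache_fixture("small_sim", function() {
    simulate_genomes(small_sim_config())
  })
}

# Study-scale cohort + split + trained ensemble, reused across test files.
standard_sim <- function() {
  cache_fixture("standard_sim", function() {
    simulate_genomes(simulation_config(seed = 1))
  })
}

standard_split <- function() {
  cache_fixture("standard_split", function() {
    sim <- standard_sim()
    part <- stratified_partition(sim, 0.7, seed = 1)
    list(train = sim[sim$genome_id %in% part$train, ],
         test = sim[sim$genome_id %in% part$test, ])
  })
}

standard_bundle <- function() {
  cache_fixture("standard_bundle", function() {
    train_ensemble(standard_split()$train, cv_config(seed = 1))
  })
}

# Join predictions back to truth by genome id (predict() sorts rows).
scored_predictions <- function(bundle, features) {
  dplyr::inner_join(predict(bundle, features),
                    features[c("genome_id", "phenotype")], by = "genome_id")
}

# Fast ensemble settings for tests that train many times.
fast_cv <- function(seed) cv_config(n_folds = 5, seed = seed)
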