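#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom randomForest randomForest
#' @importFrom kernlab ksvm
#' @importFrom nnet nnet
#' @importFrom xgboost xgb.train
#' @importFrom withr with_seed
#' @keywords internal
"_PACKAGE"

# Phenotype coding used everywhere: positive class is "Sporulating".
phenotype_levels <- c("Non-Sporulating", "Sporulating")
positive_class <- "Sporulating"

as_phenotype <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), phenotype_levels)
  if (length(bad) > 0) {
    stop("Unknown phenotype value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(phenotype_levels, collapse = " or "), ")",
         call. = FALSE)
  }
  factor(x, levels = phenotype_levels)
}

# Content hash via a normalized temp file; avoids extra dependencies and is
# stable across platforms (LF line endings, UTF-8).
hash_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, open = "wb")
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

# Deterministic sub-seed derivation so one user seed drives all stages.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2011 + (offset %% 1e6) * 7 + 1) %% 2147483629L
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

join_tokens <- function(x) paste(x, collapse = ",")

#' Gene columns of a feature table
#'
#' A feature table is a tibble with a `genome_id` column, an optional
#' `phenotype` column, and one 0/1 column per catalog gene. This helper
#' returns the gene column names in table order.
#'
#' @param features A feature tibble.
#' @return Character vector of gene column names.
#' @export
feature_gene_names <- function(features) {
  setdiff(names(features), c("genome_id", "phenotype"))
}

# Numeric genomes x genes matrix view of a feature tibble.
feature_values <- function(features) {
  genes <- feature_gene_names(features)
  m <- as.matrix(features[genes])
  storage.mode(m) <- "double"
  rownames(m) <- features$genome_id
  m
}

check_binary_features <- function(features, arg = "features") {
  if (!"genome_id" %in% names(features)) {
    stop("`", arg, "` must contain a `genome_id` column", call. = FALSE)
  }
  m <- feature_values(features)
  if (ncol(m) == 0) stop("`", arg, "` has no gene columns", call. = FALSE)
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("`", arg, "` gene columns must be 0/1 with no missing values",
         call. = FALSE)
  }
  invisible(features)
}
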