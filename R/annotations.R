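#' Parse an eggNOG-mapper style annotation table
#'
#' Reads the tab-separated annotation dialect: lines starting `#` are
#' comments except a header line starting `#query` that names the columns;
#' the `KEGG_ko` cell is `-` or a comma-joined list of `ko:KXXXXX` tokens.
#' One record is returned per data row; `-` fields become `NA`/empty.
#'
#' @param path Annotation file path.
#' @param max_evalue Optional e-value cutoff; rows with `evalue > max_evalue`
#'   are dropped (rows without an e-value are kept). The upstream annotation
#'   pipeline's identity/coverage filters are assumed already applied.
#' @return A tibble with columns `query`, `evalue`, `preferred_name`,
#'   `ko_ids` (canonical comma-joined `KXXXXX` tokens, `""` for none).
#' @export
read_emapper <- function(path, max_evalue = NULL) {
  if (!file.exists(path)) stop("Annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_idx <- grep("^#query", lines)
  if (length(header_idx) == 0) {
    stop("Annotation schema error in ", basename(path),
         ": no '#query' header line found", call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[header_idx[1]]), "\t", fixed = TRUE)[[1]]
  if (!"query" %in% header ||
      !all(c("Preferred_name", "KEGG_ko") %in% header)) {
    stop("Annotation schema error in ", basename(path),
         ": header must name 'query' plus 'Preferred_name' and 'KEGG_ko'; ",
         "observed: ", paste(header, collapse = ", "), call. = FALSE)
  }
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- tibble(query = character(), evalue = double(),
                  preferred_name = character(), ko_ids = character())
  if (length(data_lines) == 0) return(empty)

  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  get_col <- function(name) {
    j <- match(name, header)
    if (is.na(j)) return(rep(NA_character_, length(parts)))
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_,
           character(1))
  }
  dash_na <- function(x) ifelse(is.na(x) | x == "-" | x == "", NA_character_, x)
  rec <- tibble(
    query = get_col("query"),
    evalue = suppressWarnings(as.numeric(dash_na(get_col("evalue")))),
    preferred_name = dash_na(get_col("Preferred_name")),
    ko_ids = vapply(dash_na(get_col("KEGG_ko")), function(cell) {
      if (is.na(cell)) return("")
      toks <- sub("^ko:", "", split_tokens(cell))
      join_tokens(toks[grepl("^K[0-9]{5}$", toks)])
    }, character(1), USE.NAMES = FALSE)
  )
  if (!is.null(max_evalue)) {
    keep <- is.na(rec$evalue) | rec$evalue <= max_evalue
    rec <- rec[keep, ]
  }
  rec
}

# name -> column index and ko -> column index lookups for a catalog.
catalog_lookup <- function(catalog) {
  n <- nrow(catalog)
  name_idx <- stats::setNames(seq_len(n), tolower(catalog$gene_symbol))
  for (i in seq_len(n)) {
    for (a in split_tokens(catalog$aliases[i])) {
      name_idx[tolower(a)] <- i
    }
  }
  ko_idx <- integer(0)
  for (i in seq_len(n)) {
    for (k in split_tokens(catalog$ko_ids[i])) ko_idx[k] <- i
  }
  list(name = name_idx, ko = ko_idx)
}

#' Encode one genome as a presence/absence vector
#'
#' A catalog gene is marked present (1) if any annotation record matches it
#' by gene name (case-insensitive, alias-aware `Preferred_name`) or by a
#' shared KEGG Orthology identifier. Multiplicity is ignored; unmatched
#' records are ignored; genes with no matching record are 0.
#'
#' @param records Annotation tibble from [read_emapper()].
#' @param catalog A validated gene catalog.
#' @return Named integer 0/1 vector in catalog order.
#' @export
encode_genome <- function(records, catalog) {
  lookup <- catalog_lookup(catalog)
  v <- stats::setNames(integer(nrow(catalog)), catalog$gene_symbol)
  if (nrow(records) > 0) {
    hits_name <- lookup$name[tolower(records$preferred_name)]
    v[hits_name[!is.na(hits_name)]] <- 1L
    kos <- unlist(lapply(records$ko_ids, split_tokens), use.names = FALSE)
    hits_ko <- lookup$ko[kos]
    v[hits_ko[!is.na(hits_ko)]] <- 1L
  }
  v
}

#' Build a feature matrix from a directory of annotation files
#'
#' Each file becomes one genome row; the genome id is the filename stem
#' (a trailing `.emapper.annotations` or single extension is stripped).
#' Rows are sorted by `genome_id` for determinism. Missing annotations
#' encode as absence (0) — the matrix never contains missing cells.
#'
#' @param annotation_dir Directory of annotation TSVs.
#' @param catalog A validated gene catalog.
#' @param labels Optional tibble `genome_id`, `phenotype` with phenotype in
#'   `Sporulating` / `Non-Sporulating`; labels for genomes not present are
#'   dropped with a warning.
#' @param max_evalue Optional e-value filter passed to [read_emapper()].
#' @return Feature tibble: `genome_id`, optional `phenotype`, then one 0/1
#'   column per catalog gene in catalog order.
#' @export
build_feature_matrix <- function(annotation_dir, catalog, labels = NULL,
                                 max_evalue = NULL) {
  validate_catalog(catalog)
  files <- list.files(annotation_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    stop("No annotation files found in ", annotation_dir, call. = FALSE)
  }
  stems <- basename(files)
  stems <- sub("\\.emapper\\.annotations$", "", stems)
  stems <- ifelse(grepl("\\.[A-Za-z0-9]+$", stems),
                  tools::file_path_sans_ext(stems), stems)
  if (anyDuplicated(stems)) {
    stop("Duplicate genome id(s) from filenames: ",
         paste(unique(stems[duplicated(stems)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(files, function(f) {
    encode_genome(read_emapper(f, max_evalue = max_evalue), catalog)
  })
  m <- do.call(rbind, rows)
  ord <- order(stems)
  features <- dplyr::bind_cols(tibble(genome_id = stems[ord]),
                               as_tibble(m[ord, , drop = FALSE]))
  message("Encoded ", nrow(features), " genome(s); genes present per genome: ",
          paste(rowSums(feature_values(features)), collapse = ", "))
  if (!is.null(labels)) {
    features <- attach_labels(features, labels)
  }
  features
}

#' Attach phenotype labels to a feature table
#'
#' @param features Feature tibble.
#' @param labels Tibble with `genome_id` and `phenotype` columns.
#' @return Feature tibble with a `phenotype` factor column after `genome_id`.
#' @export
attach_labels <- function(features, labels) {
  if (!all(c("genome_id", "phenotype") %in% names(labels))) {
    stop("`labels` must have columns genome_id and phenotype", call. = FALSE)
  }
  unknown <- setdiff(labels$genome_id, features$genome_id)
  if (length(unknown) > 0) {
    warning("Ignoring label(s) for genome(s) not in the matrix: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  phen <- as_phenotype(labels$phenotype[match(features$genome_id,
                                              labels$genome_id)])
  dplyr::bind_cols(features["genome_id"], tibble(phenotype = phen),
                   features[feature_gene_names(features)])
}

#' Align a feature matrix to a gene catalog
#'
#' Reorders gene columns to catalog order, zero-fills catalog genes absent
#' from the input (with a warning), and drops columns unknown to the catalog
#' (with a warning). Errors if fewer than half of the catalog genes are
#' present in the input — a sign the wrong matrix was supplied.
#'
#' @param features Feature tibble with gene-symbol column names.
#' @param catalog A validated gene catalog.
#' @return Aligned feature tibble with columns in catalog order.
#' @export
align_features <- function(features, catalog) {
  validate_catalog(catalog)
  align_to_genes(features, catalog$gene_symbol)
}

align_to_genes <- function(features, gene_symbols) {
  have <- feature_gene_names(features)
  matched <- intersect(gene_symbols, have)
  if (length(matched) < length(gene_symbols) / 2) {
    stop("Only ", length(matched), " of ", length(gene_symbols),
         " expected genes present in the input matrix; ",
         "this does not look like a matrix over the same gene catalog",
         call. = FALSE)
  }
  missing <- setdiff(gene_symbols, have)
  extra <- setdiff(have, gene_symbols)
  if (length(missing) > 0) {
    warning("Zero-filling ", length(missing), " catalog gene(s) absent from ",
            "the input: ", paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
    for (g in missing) features[[g]] <- 0L
  }
  if (length(extra) > 0) {
    warning("Dropping ", length(extra), " column(s) unknown to the catalog: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  meta <- intersect(c("genome_id", "phenotype"), names(features))
  features[c(meta, gene_symbols)]
}

#' Read/write feature matrices and label tables
#'
#' The feature-matrix CSV has `genome_id` as first column then one 0/1
#' column per gene; phenotype labels travel in a separate two-column TSV
#' (`genome_id`, `phenotype`).
#'
#' @param features Feature tibble.
#' @param path File path.
#' @param labels Optional labels tibble to attach on read.
#' @return The tibble read, or `path` invisibly for writers.
#' @export
write_feature_matrix <- function(features, path) {
  out <- features[c("genome_id", feature_gene_names(features))]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, labels = NULL) {
  features <- readr::read_csv(path, col_types = readr::cols(
    genome_id = "c", .default = "i"), progress = FALSE)
  check_binary_features(features)
  if (!is.null(labels)) features <- attach_labels(features, labels)
  features
}

#' @rdname write_feature_matrix
#' @export
read_labels <- function(path) {
  labs <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("genome_id", "phenotype") %in% names(labs))) {
    stop("Labels file must have columns genome_id and phenotype", call. = FALSE)
  }
  labs$phenotype <- as.character(as_phenotype(labs$phenotype))
  labs
}

#' @rdname write_feature_matrix
#' @export
write_labels <- function(features, path) {
  labs <- tibble(genome_id = features$genome_id,
                 phenotype = as.character(features$phenotype))
  readr::write_tsv(labs, path, progress = FALSE)
  invisible(path)
}
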