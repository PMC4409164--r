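# Plain-text interchange: OTU tables as TSV (taxonomy column
# "phylum;family") with a sample-metadata TSV, environmental matrices and
# distance matrices as CSV, truth records as JSON, optional BIOM (JSON)
# input.

#' Write an OTU table as TSV
#'
#' Writes two files: `<path>` with rows = OTUs, columns = samples plus a
#' final `taxonomy` column (`phylum;family`), and `<path>.samples.tsv` with
#' the sample metadata (`sample`, `station`, `replicate`, `estuary`).
#'
#' @param table An [otu_table()].
#' @param path Output TSV path.
#' @return Invisibly, the two paths written.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- as.data.frame(table$counts, check.names = FALSE)
  df <- cbind(otu = rownames(table$counts), df,
              taxonomy = paste(table$taxonomy$phylum, table$taxonomy$family,
                               sep = ";"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(path, ".samples.tsv")
  write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read an OTU table from TSV
#'
#' Inverse of [write_otu_table()]; `read_otu_table(write_otu_table(x))`
#' round-trips.
#'
#' @param path TSV path (expects `<path>.samples.tsv` alongside, unless
#'   `samples_path` is given).
#' @param samples_path Optional explicit sample-metadata path.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, samples_path = paste0(path, ".samples.tsv")) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("otu", "taxonomy") %in% names(df)))
    stopf("OTU TSV must have `otu` and `taxonomy` columns")
  tax_split <- strsplit(df$taxonomy, ";", fixed = TRUE)
  bad <- which(lengths(tax_split) != 2)
  if (length(bad))
    stopf("malformed taxonomy string at line %d: %s", bad[1] + 1,
          df$taxonomy[bad[1]])
  scols <- setdiff(names(df), c("otu", "taxonomy"))
  counts <- as.matrix(df[, scols, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "numeric")
  if (anyNA(counts)) stopf("non-numeric count value in %s", path)
  rownames(counts) <- df$otu
  taxonomy <- data.frame(otu = df$otu,
                         phylum = vapply(tax_split, `[`, "", 1),
                         family = vapply(tax_split, `[`, "", 2))
  samples <- read.delim(samples_path)
  otu_table(counts, taxonomy, samples)
}

#' Read an OTU table from a JSON BIOM file
#'
#' Requires the `biomformat` package. Taxonomy is taken from the
#' observation metadata (first two columns: phylum, family); sample
#' metadata from the first three sample-metadata columns (station,
#' replicate, estuary) — the JSON BIOM dialect does not preserve metadata
#' column names, so order is the contract.
#'
#' @param path BIOM (JSON) file path.
#' @return An [otu_table()].
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stopf("reading BIOM files requires the `biomformat` package")
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  sm <- biomformat::sample_metadata(b)
  if (is.null(om)) stopf("BIOM file lacks observation (taxonomy) metadata")
  om <- as.data.frame(om)
  taxonomy <- data.frame(otu = rownames(counts),
                         phylum = as.character(om[[1]]),
                         family = as.character(om[[2]]))
  sm <- as.data.frame(sm)
  if (is.null(sm) || ncol(sm) < 3)
    stopf("BIOM sample metadata must carry station, replicate, estuary")
  sm <- sm[match(colnames(counts), rownames(sm)), , drop = FALSE]
  samples <- data.frame(sample = colnames(counts),
                        station = as.character(sm[[1]]),
                        replicate = as.integer(sm[[2]]),
                        estuary = as.character(sm[[3]]))
  otu_table(counts, taxonomy, samples)
}

#' Write / read an environmental matrix CSV
#'
#' @param env An `env_matrix` data.frame.
#' @param path CSV path.
#' @return `write_env_matrix`: the path, invisibly. `read_env_matrix`: the
#'   `env_matrix`.
#' @export
write_env_matrix <- function(env, path) {
  write.csv(as.data.frame(env), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_matrix
#' @export
read_env_matrix <- function(path) {
  d <- read.csv(path)
  miss <- setdiff(c("station", env_driver_names()), names(d))
  if (length(miss))
    stopf("env matrix CSV lacks column(s): %s", paste(miss, collapse = ", "))
  class(d) <- c("env_matrix", "data.frame")
  d
}

#' Write / read a labelled square distance matrix CSV
#'
#' @param D Symmetric matrix with labels.
#' @param path CSV path.
#' @return `write_distance_matrix`: the path, invisibly.
#'   `read_distance_matrix`: the validated matrix.
#' @export
write_distance_matrix <- function(D, path) {
  D <- check_distmat(D)
  write.csv(data.frame(label = rownames(D), D, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$label
  check_distmat(m)
}

#' Write a truth record as JSON
#'
#' @param truth A `truth_record` from [generate_community()].
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(
    list(otu = truth$otu,
         env = as.data.frame(truth$env),
         zones = as.list(truth$zones)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
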