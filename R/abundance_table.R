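#' Taxon-by-sample abundance table
#'
#' The central container of the package: a non-negative integer count matrix
#' (rows = taxa, columns = samples) together with per-sample metadata (at
#' least a successional `stage` label and a `replicate` number) and per-taxon
#' metadata (lineage ranks plus an `is_cyanobacterium` flag used by the
#' focal-group network contrasts).
#'
#' @param counts numeric matrix of non-negative counts, taxa in rows and
#'   samples in columns; `rownames`/`colnames` identify taxa and samples.
#' @param sample_meta data.frame with columns `sample_id`, `stage`,
#'   `replicate`; one row per column of `counts`.
#' @param taxon_meta data.frame with column `taxon_id`, any lineage-rank
#'   columns (e.g. `kingdom`, `phylum`, `family`) and logical
#'   `is_cyanobacterium`; one row per row of `counts`.
#'
#' @return an object of class `abundance_table` (a list with elements
#'   `counts`, `sample_meta`, `taxon_meta`).
#' @export
abundance_table <- function(counts, sample_meta, taxon_meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_arg("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_arg("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    abort_arg("taxon and sample IDs must be unique")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  taxon_meta <- as.data.frame(taxon_meta, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "stage")
  if (!all(need_s %in% names(sample_meta)))
    abort_arg("sample_meta needs columns: ", paste(need_s, collapse = ", "))
  if (!"taxon_id" %in% names(taxon_meta))
    abort_arg("taxon_meta needs a taxon_id column")
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    abort_arg("sample_meta$sample_id must match colnames(counts)")
  if (!setequal(taxon_meta$taxon_id, rownames(counts)))
    abort_arg("taxon_meta$taxon_id must match rownames(counts)")
  if (anyNA(sample_meta$stage)) abort_arg("every sample needs a stage label")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  taxon_meta <- taxon_meta[match(rownames(counts), taxon_meta$taxon_id), ,
                           drop = FALSE]
  rownames(sample_meta) <- NULL
  rownames(taxon_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta,
                 taxon_meta = taxon_meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  stages: ", paste(unique(x$sample_meta$stage), collapse = ", "), "\n",
      sep = "")
  if ("is_cyanobacterium" %in% names(x$taxon_meta))
    cat("  cyanobacterial taxa: ", sum(x$taxon_meta$is_cyanobacterium), "\n",
        sep = "")
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param table an [abundance_table].
#' @return matrix of column-wise proportions.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  sweep(table$counts, 2, colSums(table$counts), "/")
}

#' Subset an abundance table by sample or by taxon
#'
#' @param table an [abundance_table].
#' @param samples character vector of sample IDs, or `NULL`.
#' @param taxa character vector of taxon IDs, or `NULL`.
#' @param stage keep only samples of this stage (applied after `samples`).
#' @return an [abundance_table].
#' @export
subset_table <- function(table, samples = NULL, taxa = NULL, stage = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  counts <- table$counts
  sm <- table$sample_meta
  tm <- table$taxon_meta
  if (!is.null(samples)) {
    counts <- counts[, colnames(counts) %in% samples, drop = FALSE]
  }
  if (!is.null(stage)) {
    keep <- sm$sample_id[sm$stage %in% stage]
    counts <- counts[, colnames(counts) %in% keep, drop = FALSE]
  }
  if (!is.null(taxa)) {
    counts <- counts[rownames(counts) %in% taxa, , drop = FALSE]
  }
  if (ncol(counts) == 0L) abort_arg("no samples left after subsetting")
  if (nrow(counts) == 0L) abort_arg("no taxa left after subsetting")
  abundance_table(counts,
                  sm[sm$sample_id %in% colnames(counts), , drop = FALSE],
                  tm[tm$taxon_id %in% rownames(counts), , drop = FALSE])
}

#' Write an abundance table to the package's TSV dialect
#'
#' Three files: a count table (rows = taxa, header row of sample IDs), a
#' taxonomy table (`taxon_id`, lineage ranks, `is_cyanobacterium` coded 0/1)
#' and a sample-metadata table (`sample_id`, `stage`, `replicate`).
#'
#' @param table an [abundance_table].
#' @param counts_path,taxonomy_path,metadata_path output TSV paths.
#' @return invisibly, the three paths.
#' @export
write_abundance_table <- function(table, counts_path, taxonomy_path,
                                  metadata_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tm <- table$taxon_meta
  if ("is_cyanobacterium" %in% names(tm))
    tm$is_cyanobacterium <- as.integer(tm$is_cyanobacterium)
  utils::write.table(tm, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$sample_meta, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, taxonomy_path, metadata_path))
}

#' Read an abundance table from the package's TSV dialect
#'
#' @param counts_path,taxonomy_path,metadata_path TSV paths as written by
#'   [write_abundance_table()].
#' @return an [abundance_table].
#' @export
read_abundance_table <- function(counts_path, taxonomy_path, metadata_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  tm <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if ("is_cyanobacterium" %in% names(tm))
    tm$is_cyanobacterium <- as.logical(tm$is_cyanobacterium)
  sm <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sm$sample_id <- as.character(sm$sample_id)
  abundance_table(counts, sm, tm)
}
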