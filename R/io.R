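# Readers and writers for the pipeline's on-disk formats: per-cell FASTA,
# bulk FASTQ, counts as TSV / MatrixMarket, truth tables, AIRR-style
# rearrangement TSV, clonotype tables and YAML configs.

#' Write per-cell transcripts as FASTA with barcode-tagged headers
#'
#' Headers are `barcode|transcript_id`, so one file carries the whole cohort.
#'
#' @param x A `sim_cohort` or named list of per-cell transcript vectors.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cell_fasta <- function(x, path) {
  cells <- if (inherits(x, "sim_cohort")) x$transcripts else x
  seqs <- unlist(cells, use.names = FALSE)
  ids <- unlist(lapply(names(cells), function(bc)
    paste(bc, names(cells[[bc]]), sep = "|")), use.names = FALSE)
  set <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a barcode-tagged per-cell FASTA back into a transcript list
#' @param path FASTA path written by [write_cell_fasta()].
#' @return Named list of per-cell named transcript vectors.
#' @export
read_cell_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(set), "|", fixed = TRUE)
  bc <- vapply(ids, `[`, "", 1)
  tx <- vapply(ids, `[`, "", 2)
  seqs <- as.character(set)
  out <- split(setNames(seqs, tx), bc)
  out[unique(bc)]
}

#' Write bulk repertoire reads as FASTQ (Phred+33)
#' @param bulk A `bulk_reads` object or named character vector.
#' @param path Output FASTQ path.
#' @param quality Constant per-base quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_bulk_fastq <- function(bulk, path, quality = "I") {
  reads <- if (inherits(bulk, "bulk_reads")) bulk$reads else bulk
  quals <- vapply(nchar(reads), function(n)
    paste(rep(quality, n), collapse = ""), "")
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of reads
#' @param path FASTQ path.
#' @return Named character vector.
#' @export
read_bulk_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(set), names(set))
}

#' Write / read a gene-by-cell count matrix as TSV
#'
#' Genes in rows with a `gene` index column; cells in columns.
#'
#' @param m A `count_matrix` (or plain matrix).
#' @param path TSV path.
#' @return `path` invisibly (writer); a `count_matrix` (reader).
#' @export
write_counts_tsv <- function(m, path) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  count_matrix(counts)
}

#' Write a count matrix in MatrixMarket form
#'
#' Writes `<stem>.mtx` plus `<stem>.genes.tsv` and `<stem>.barcodes.tsv`.
#'
#' @param m A `count_matrix`.
#' @param stem Path stem for the three files.
#' @return The `.mtx` path, invisibly.
#' @export
write_counts_mtx <- function(m, stem) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
  writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
  writeLines(colnames(counts), paste0(stem, ".barcodes.tsv"))
  invisible(mtx)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  counts <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(counts) <- readLines(paste0(stem, ".genes.tsv"))
  colnames(counts) <- readLines(paste0(stem, ".barcodes.tsv"))
  storage.mode(counts) <- "integer"
  count_matrix(counts)
}

#' Write / read an AIRR-style rearrangement table
#'
#' Columns: `cell_id`, `locus`, `v_call`, `j_call`, `junction`,
#' `junction_aa`, `cdr3_aa`, `v_identity`, `productive`, `doublet`.
#'
#' @param annotations A `cell_annotations` object or its `$table`.
#' @param path TSV path.
#' @return `path` invisibly (writer); the rearrangement data.frame (reader).
#' @export
write_rearrangements <- function(annotations, path) {
  tab <- if (inherits(annotations, "cell_annotations")) annotations$table
         else annotations
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_rearrangements
#' @export
read_rearrangements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("productive", "doublet"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a clonotype / clone table as TSV
#' @param x A `clone_call_result` or `clonotype_set`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(x, path) {
  tab <- if (inherits(x, "clone_call_result")) x$clonotypes else
    as.data.frame(x)
  tab$members <- vapply(tab$members, paste, "", collapse = ";")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth table of a simulated cohort as TSV
#' @param cohort A `sim_cohort`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(cohort, path) {
  write.table(cohort$truth$labels, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation config as YAML
#' @param cfg A `simulation_config`.
#' @param path YAML path.
#' @return `path` invisibly (writer); a `simulation_config` (reader).
#' @export
write_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$planted_substitutions <- as.list(x$planted_substitutions)
  x$marker_effects <- as.list(x$marker_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$planted_substitutions <- data.frame(
    position = as.integer(x$planted_substitutions$position),
    germline = as.character(x$planted_substitutions$germline),
    mutant = as.character(x$planted_substitutions$mutant),
    stringsAsFactors = FALSE)
  x$marker_effects <- unlist(x$marker_effects)
  do.call(simulation_config, x)
}

#' Write a complete simulated cohort to a directory
#'
#' Emits `cells.fasta`, `germline.fasta`, `truth.tsv`, `counts.tsv`,
#' `counts.mtx` (+ index files), `bulk.fastq` and `config.yaml`, as present.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_fasta(cohort, file.path(dir, "cells.fasta"))
  write_germline_fasta(cohort$reference, file.path(dir, "germline.fasta"))
  write_truth_tsv(cohort, file.path(dir, "truth.tsv"))
  write_config_yaml(cohort$config, file.path(dir, "config.yaml"))
  if (!is.null(cohort$counts)) {
    write_counts_tsv(cohort$counts, file.path(dir, "counts.tsv"))
    write_counts_mtx(cohort$counts, file.path(dir, "counts"))
  }
  if (!is.null(cohort$bulk))
    write_bulk_fastq(cohort$bulk, file.path(dir, "bulk.fastq"))
  invisible(dir)
}
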