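#' Read a FASTA file
#'
#' Multi-line FASTA, case-insensitive; sequences are upper-cased and record
#' order is preserved.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  if (length(x) == 0L) stop("empty FASTQ file: ", path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con)
}

#' Write reads to FASTQ (constant placeholder qualities)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  quals <- vapply(nchar(seqs), function(k)
    paste(rep("I", k), collapse = ""), "")
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", quals), con)
}

.tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Save an index to a directory
#'
#' Writes a versioned plain-text bundle: `meta.json` (format version,
#' strand mode, sizes, optional cutoff), `docs.tsv` (document catalog),
#' `runs.tsv` (move table rows with thresholds and color IDs),
#' `colors.tsv` (color table, sparse member lists) and `taxonomy.tsv` when
#' present. Serialization is deterministic: re-saving an unchanged bundle
#' produces identical bytes. The suffix structures are not persisted; a
#' loaded index supports querying and classification but not
#' [color_fidelity()].
#'
#' @param index A built index.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- index$meta
  meta$cutoff <- index$cutoff
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  .tsv_write(index$docs, file.path(dir, "docs.tsv"))
  runs <- index$runs[, c("start", "length", "char", "dest_run",
                         "dest_offset", "color_id")]
  thr <- index$thresholds
  colnames(thr) <- paste0("thr_", colnames(thr))
  .tsv_write(cbind(runs, as.data.frame(thr)), file.path(dir, "runs.tsv"))
  colors <- data.frame(
    color_id = seq_along(index$colors) - 1L,
    docs = vapply(index$colors, paste, "", collapse = ","))
  .tsv_write(colors, file.path(dir, "colors.tsv"))
  if (!is.null(index$taxonomy))
    write_taxonomy(index$taxonomy, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' Load an index saved with [save_index()]
#'
#' Verifies the format version and that every component is present;
#' derived structures (nearest-run tables, color pointers, character
#' counts) are rebuilt deterministically. `load_index(save_index(x))`
#' classifies any read identically to `x`.
#'
#' @param dir Directory written by [save_index()].
#' @return A `cbwt_index` (without suffix structures).
#' @export
load_index <- function(dir) {
  need <- c("meta.json", "docs.tsv", "runs.tsv", "colors.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("incomplete index bundle, missing: ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format_version, .INDEX_FORMAT_VERSION))
    stop("index format version mismatch: ", meta$format_version)
  docs <- utils::read.delim(file.path(dir, "docs.tsv"),
                            stringsAsFactors = FALSE)
  rt <- utils::read.delim(file.path(dir, "runs.tsv"),
                          stringsAsFactors = FALSE)
  req <- c("start", "length", "char", "dest_run", "dest_offset", "color_id",
           "thr_A", "thr_C", "thr_G", "thr_T")
  if (!all(req %in% names(rt)) || nrow(rt) != meta$r)
    stop("corrupt or truncated runs.tsv")
  ct <- utils::read.delim(file.path(dir, "colors.tsv"),
                          stringsAsFactors = FALSE)
  if (nrow(ct) != meta$n_colors) stop("corrupt or truncated colors.tsv")
  ct$docs[is.na(ct$docs)] <- ""
  colors <- lapply(strsplit(ct$docs, ",", fixed = TRUE), as.integer)
  colors <- lapply(colors, function(x) x[!is.na(x)])
  tax_path <- file.path(dir, "taxonomy.tsv")
  tax <- if (file.exists(tax_path)) read_taxonomy(tax_path) else NULL

  runs <- data.frame(run = seq_len(nrow(rt)) - 1L, start = rt$start,
                     length = rt$length, char = rt$char,
                     stringsAsFactors = FALSE)
  codes <- match(runs$char, .ALPHABET) - 1L
  if (anyNA(codes)) stop("corrupt runs.tsv: bad run character")
  char_counts <- vapply(0:4, function(c)
    sum(runs$length[codes == c]), 0)
  char_counts <- stats::setNames(as.integer(char_counts), .ALPHABET)
  runs$dest_run <- rt$dest_run
  runs$dest_offset <- rt$dest_offset
  runs$color_id <- rt$color_id
  thr <- as.matrix(rt[, c("thr_A", "thr_C", "thr_G", "thr_T")])
  colnames(thr) <- c("A", "C", "G", "T")
  nr <- cpp_nearest_runs(codes)
  sizes <- vapply(colors, length, 1L)
  color_docs <- as.integer(unlist(colors, use.names = FALSE))
  if (is.null(color_docs)) color_docs <- integer(0)
  structure(list(
    meta = list(format_version = meta$format_version,
                strand_mode = meta$strand_mode, n = meta$n, r = meta$r,
                n_colors = meta$n_colors, n_docs = meta$n_docs),
    docs = docs, taxonomy = tax, char_counts = char_counts, runs = runs,
    thresholds = thr, nearest_up = nr$up, nearest_down = nr$down,
    colors = colors, color_ptr = as.integer(cumsum(c(0L, sizes))),
    color_docs = color_docs,
    cutoff = if (is.null(meta$cutoff)) NULL else as.numeric(meta$cutoff),
    structures = NULL
  ), class = "cbwt_index")
}

#' Write a classification report TSV
#'
#' One row per read, stable column order: `read_id`, `status` (`C`/`U`),
#' `taxon_id`, `taxon_rank`, `average_pml`, `reported_docs`, `top_scores`.
#'
#' @param records Data.frame from [classify_reads()].
#' @param path Output path.
#' @export
write_report <- function(records, path) {
  cols <- c("read_id", "status", "taxon_id", "taxon_rank", "average_pml",
            "reported_docs", "top_scores")
  .tsv_write(records[, cols, drop = FALSE], path)
}

#' Read a classification report TSV
#'
#' @param path Report path as written by [write_report()].
#' @return Data.frame of records.
#' @export
read_report <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(read_id = "character",
                                          status = "character",
                                          taxon_rank = "character",
                                          reported_docs = "character",
                                          top_scores = "character"))
  out$reported_docs[is.na(out$reported_docs)] <- ""
  out$top_scores[is.na(out$top_scores)] <- ""
  out
}

#' Write a two-column classifier-style summary
#'
#' Interoperability output: `read_id` and assigned `taxon_id` (0 when
#' unclassified), one row per read.
#'
#' @param records Data.frame from [classify_reads()].
#' @param path Output path.
#' @export
write_summary <- function(records, path) {
  taxon <- ifelse(is.na(records$taxon_id), 0L, records$taxon_id)
  .tsv_write(data.frame(read_id = records$read_id, taxon_id = taxon), path)
}
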