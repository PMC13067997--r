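#' Create a reference document collection
#'
#' A document is the most specific classification unit of the index: a named
#' group of one or more nucleotide sequences (for example all sequences of a
#' genome, or all genomes of a species), optionally mapped to a taxonomy
#' node. Document IDs are assigned `0..D-1` in list order.
#'
#' Sequences are sanitized on construction: upper-cased and split at any
#' non-`ACGT` character (see [sanitize_sequences()]). A document whose
#' sequences are all empty after sanitization is an error.
#'
#' @param docs Named list; each element is a character vector of nucleotide
#'   sequences belonging to one document.
#' @param taxon_id Optional integer vector (one per document) of taxonomy
#'   node IDs.
#' @return An object of class `cbwt_collection` with elements `docs`
#'   (data.frame `doc_id`, `name`, `taxon_id`) and `sequences` (list of
#'   sanitized fragment vectors, one per document).
#' @export
reference_collection <- function(docs, taxon_id = NULL) {
  if (!is.list(docs) || length(docs) == 0L)
    stop("'docs' must be a non-empty named list of sequence vectors")
  nm <- names(docs)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("documents must have unique non-empty names")
  if (is.null(taxon_id)) taxon_id <- rep(NA_integer_, length(docs))
  stopifnot(length(taxon_id) == length(docs))
  sequences <- lapply(docs, function(s) unlist(sanitize_sequences(s)))
  empty <- vapply(sequences, length, 1L) == 0L
  if (any(empty))
    stop("document(s) empty after sanitization: ",
         paste(nm[empty], collapse = ", "))
  structure(
    list(
      docs = data.frame(doc_id = seq_along(docs) - 1L, name = nm,
                        taxon_id = as.integer(taxon_id),
                        stringsAsFactors = FALSE),
      sequences = sequences
    ),
    class = "cbwt_collection"
  )
}

#' @export
print.cbwt_collection <- function(x, ...) {
  cat("Reference collection:", nrow(x$docs), "documents,",
      sum(vapply(x$sequences, function(s) sum(nchar(s)), 1)), "bp\n")
  invisible(x)
}

#' Concatenate a document collection into a single terminated text
#'
#' Documents are concatenated in document-ID order; with
#' `strand_mode = "with_reverse_complement"` the reverse complement of each
#' document is appended directly after its forward sequence, under the same
#' document ID. A single terminator `$` is appended at the end; there are no
#' per-document separators.
#'
#' @param collection A [reference_collection()].
#' @param strand_mode `"with_reverse_complement"` (default) or
#'   `"forward_only"`.
#' @return A list with `text` (character string ending in `$`), `n` (its
#'   length), and `boundaries`, a data.frame of 0-based half-open intervals
#'   (`start`, `end`, `doc_id`) covering `[0, n-1)`.
#' @examples
#' coll <- reference_collection(list(D1 = "AAC", D2 = "AAG"))
#' concatenate_documents(coll, "forward_only")$text  # "AACAAG$"
#' @export
concatenate_documents <- function(collection,
                                  strand_mode = c("with_reverse_complement",
                                                  "forward_only")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(collection, "cbwt_collection"))
  pieces <- character(0)
  starts <- integer(0)
  doc_ids <- integer(0)
  pos <- 0L
  for (i in seq_len(nrow(collection$docs))) {
    frags <- collection$sequences[[i]]
    if (strand_mode == "with_reverse_complement") {
      # appending RCs of the fragments in reverse order yields the RC of the
      # whole document concatenation
      frags <- c(frags, vapply(rev(frags), reverse_complement, ""))
    }
    for (f in frags) {
      pieces <- c(pieces, f)
      starts <- c(starts, pos)
      doc_ids <- c(doc_ids, collection$docs$doc_id[i])
      pos <- pos + nchar(f)
    }
  }
  text <- paste0(paste(pieces, collapse = ""), "$")
  boundaries <- data.frame(start = starts,
                           end = starts + nchar(pieces),
                           doc_id = doc_ids)
  list(text = text, n = nchar(text), boundaries = boundaries,
       strand_mode = strand_mode)
}
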