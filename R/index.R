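.INDEX_FORMAT_VERSION <- "1.0"

#' Build a colored move-structure index
#'
#' Constructs the full index over a document collection: concatenated text,
#' suffix array, BWT, LCP array, document array, run-length encoding,
#' LCP-based repositioning thresholds, the move table (per-run LF
#' destinations), and the deduplicated color table.
#'
#' @param collection A [reference_collection()].
#' @param taxonomy Optional [taxonomy()] object; document `taxon_id`s must
#'   be nodes of it.
#' @param strand_mode `"with_reverse_complement"` (default: each document's
#'   reverse complement is indexed under the same document ID, so a single
#'   query pass covers both strands) or `"forward_only"`.
#' @param keep_structures Keep the suffix structures (text, suffix array,
#'   LCP, document array) inside the object. Required by the fidelity
#'   diagnostics ([color_fidelity()]); adds O(n) memory.
#' @return An object of class `cbwt_index`.
#' @examples
#' coll <- reference_collection(list(D1 = "AAC", D2 = "AAG"))
#' idx <- build_index(coll, strand_mode = "forward_only")
#' index_stats(idx)$r
#' @export
build_index <- function(collection, taxonomy = NULL,
                        strand_mode = c("with_reverse_complement",
                                        "forward_only"),
                        keep_structures = TRUE) {
  strand_mode <- match.arg(strand_mode)
  cat_ <- concatenate_documents(collection, strand_mode)
  sa <- build_suffix_array(cat_$text)
  bwt <- build_bwt(cat_$text, sa)
  lcp <- build_lcp(cat_$text, sa)
  doc_array <- build_document_array(sa, cat_$boundaries)
  runs <- run_length_encode(bwt)
  thr <- compute_thresholds(runs, lcp, bwt)
  move <- build_move_table(runs, bwt)
  run_colors <- compute_run_colors(runs, doc_array)
  ct <- deduplicate_colors(run_colors)
  move$color_id <- ct$run_color_id

  codes <- encode_dna(bwt)
  char_counts <- tabulate(codes + 1L, nbins = 5L)
  names(char_counts) <- .ALPHABET
  nr <- cpp_nearest_runs(match(runs$char, .ALPHABET) - 1L)
  sizes <- vapply(ct$colors, length, 1L)
  color_ptr <- as.integer(cumsum(c(0L, sizes)))
  color_docs <- as.integer(unlist(ct$colors, use.names = FALSE))
  if (is.null(color_docs)) color_docs <- integer(0)

  if (!is.null(taxonomy)) {
    known <- collection$docs$taxon_id %in% taxonomy$nodes$node_id
    if (any(!known & !is.na(collection$docs$taxon_id)))
      stop("document taxon_id not present in taxonomy")
  }

  structure(list(
    meta = list(format_version = .INDEX_FORMAT_VERSION,
                strand_mode = strand_mode, n = cat_$n, r = nrow(runs),
                n_colors = length(ct$colors), n_docs = nrow(collection$docs)),
    docs = collection$docs,
    taxonomy = taxonomy,
    char_counts = char_counts,
    runs = move,
    thresholds = thr,
    nearest_up = nr$up,
    nearest_down = nr$down,
    colors = ct$colors,
    color_ptr = color_ptr,
    color_docs = color_docs,
    cutoff = NULL,
    structures = if (keep_structures) {
      cum <- .run_cumulative_counts(move)
      list(text = cat_$text, sa = sa, bwt = bwt, lcp = lcp,
           doc_array = doc_array, boundaries = cat_$boundaries, run_cum = cum)
    }
  ), class = "cbwt_index")
}

.run_cumulative_counts <- function(runs) {
  r <- nrow(runs)
  cum <- matrix(0L, nrow = r + 1L, ncol = 5L)
  code <- match(runs$char, .ALPHABET)
  for (c in 1:5) {
    inc <- ifelse(code == c, runs$length, 0L)
    cum[, c] <- as.integer(cumsum(c(0L, inc)))
  }
  cum
}

#' @export
print.cbwt_index <- function(x, ...) {
  cat("Colored move-structure index\n")
  cat(sprintf("  n = %d, r = %d (n/r = %.2f)\n", x$meta$n, x$meta$r,
              x$meta$n / x$meta$r))
  cat(sprintf("  |D| = %d documents, |C| = %d colors (r/|C| = %.2f)\n",
              x$meta$n_docs, x$meta$n_colors, x$meta$r / x$meta$n_colors))
  cat("  strand mode:", x$meta$strand_mode, "\n")
  if (!is.null(x$cutoff)) cat(sprintf("  binary cutoff: %.4f\n", x$cutoff))
  invisible(x)
}
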