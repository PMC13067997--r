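#' Compute per-run colors
#'
#' The color of a run is the set of distinct document IDs among its BWT
#' rows (set semantics: multiplicity is not recorded). The no-document
#' sentinel (the terminator row) contributes nothing, so a run consisting
#' solely of the terminator row has the empty color.
#'
#' @param runs Run table from [run_length_encode()].
#' @param doc_array Document array from [build_document_array()].
#' @return List (one element per run) of sorted integer vectors of document
#'   IDs.
#' @export
compute_run_colors <- function(runs, doc_array) {
  if (sum(runs$length) != length(doc_array))
    stop("doc_array inconsistent with runs")
  cpp_run_doc_sets(as.integer(doc_array), runs$start, runs$length)
}

#' Deduplicate run colors into a color table
#'
#' Distinct colors receive stable IDs in first-occurrence order; each run
#' stores only its color ID.
#'
#' @param run_colors List of per-run document-ID sets from
#'   [compute_run_colors()].
#' @return List with `colors` (list of distinct sorted document-ID sets,
#'   indexed by color ID `0..|C|-1`), `run_color_id` (integer vector, one
#'   per run), and `stats` (`n_colors`, `r`, `r_over_c`, `b` = mean set
#'   size).
#' @export
deduplicate_colors <- function(run_colors) {
  keys <- vapply(run_colors, paste, "", collapse = ",")
  first <- !duplicated(keys)
  ids <- match(keys, keys[first]) - 1L
  colors <- run_colors[first]
  r <- length(run_colors)
  list(colors = colors,
       run_color_id = ids,
       stats = list(n_colors = length(colors), r = r,
                    r_over_c = r / length(colors),
                    b = mean(vapply(colors, length, 1L))))
}

#' Encode a color densely or sparsely
#'
#' Dense: a `|D|`-bit presence vector (bit `d` set iff document `d` is in
#' the color). Sparse: the sorted offsets of the set bits. The reported
#' sizes follow the usual accounting: `|D|` bits for dense, one integer per
#' member for sparse.
#'
#' @param color Sorted integer vector of document IDs.
#' @param mode `"dense"` or `"sparse"`.
#' @param n_docs Size of the document universe `|D|`.
#' @return List with `mode`, `encoding` (logical vector for dense, integer
#'   offsets for sparse), `size_bits` (dense) or `size_integers` (sparse).
#' @export
encode_color <- function(color, mode = c("dense", "sparse"), n_docs) {
  mode <- match.arg(mode)
  color <- as.integer(color)
  if (length(color) && (min(color) < 0L || max(color) >= n_docs))
    stop("document ID outside universe 0..|D|-1")
  if (mode == "dense") {
    bits <- logical(n_docs)
    bits[color + 1L] <- TRUE
    list(mode = mode, encoding = bits, size_bits = n_docs)
  } else {
    list(mode = mode, encoding = sort(color), size_integers = length(color))
  }
}

#' Decode an encoded color
#'
#' Inverse of [encode_color()]: `decode_color(encode_color(x, ...))` equals
#' `x` for either mode.
#'
#' @param encoded Result of [encode_color()].
#' @return Sorted integer vector of document IDs.
#' @export
decode_color <- function(encoded) {
  if (encoded$mode == "dense") which(encoded$encoding) - 1L
  else as.integer(encoded$encoding)
}

#' Index summary statistics
#'
#' Diagnostics of a built index: text length `n`, run count `r`, distinct
#' color count `|C|`, the compression ratios `n/r` and `r/|C|`, the mean
#' color occupancy `b`, the dense (`|C| x |D|` bits) and sparse (`|C| x b`
#' integers) color-table sizes, and the color frequency distribution (runs
#' per color, sorted descending, with cumulative run coverage).
#'
#' @param index A built index (see [build_index()]).
#' @return List with scalar fields `n`, `r`, `n_docs`, `n_colors`,
#'   `n_over_r`, `r_over_c`, `b`, `dense_bits`, `sparse_integers`, and a
#'   data.frame `color_freq` (`color_id`, `runs`, `cum_run_fraction`).
#' @export
index_stats <- function(index) {
  r <- nrow(index$runs)
  n_colors <- length(index$colors)
  n_docs <- nrow(index$docs)
  b <- mean(vapply(index$colors, length, 1L))
  freq <- tabulate(index$runs$color_id + 1L, nbins = n_colors)
  ord <- order(freq, decreasing = TRUE)
  color_freq <- data.frame(color_id = ord - 1L, runs = freq[ord])
  color_freq$cum_run_fraction <- cumsum(color_freq$runs) / r
  list(n = index$meta$n, r = r, n_docs = n_docs, n_colors = n_colors,
       n_over_r = index$meta$n / r, r_over_c = r / n_colors, b = b,
       dense_bits = n_colors * n_docs,
       sparse_integers = n_colors * b,
       color_freq = color_freq)
}
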