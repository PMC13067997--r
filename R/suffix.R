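.check_terminated <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  term <- which(chars == "$")
  if (length(term) != 1L || term != length(chars))
    stop("text must contain exactly one '$', at the final position")
  invisible(chars)
}

#' Build the suffix array of a terminated text
#'
#' Lexicographic order of all suffixes of `text`, computed by prefix
#' doubling (O(n log^2 n), robust to highly repetitive inputs). Positions
#' are 0-based.
#'
#' @param text A character string over `ACGT` ending in a unique `$`.
#' @return Integer vector: a permutation of `0..n-1`.
#' @examples
#' build_suffix_array("AACAAG$")  # 6 0 3 1 4 2 5
#' @export
build_suffix_array <- function(text) {
  .check_terminated(text)
  cpp_suffix_array(encode_dna(text))
}

#' Build the BWT from a text and its suffix array
#'
#' `bwt[i] = text[(sa[i] - 1) mod n]`: the character preceding each sorted
#' suffix, with wraparound at the start of the text.
#'
#' @param text Terminated text.
#' @param suffix_array Its suffix array (0-based).
#' @return A character string of length `n`.
#' @examples
#' build_bwt("AACAAG$", build_suffix_array("AACAAG$"))  # "G$CAAAA"
#' @export
build_bwt <- function(text, suffix_array) {
  n <- nchar(text)
  if (length(suffix_array) != n) stop("suffix array length mismatch")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  paste(chars[((suffix_array - 1L) %% n) + 1L], collapse = "")
}

#' Build the LCP array
#'
#' `lcp[i]` is the length of the longest common prefix of the suffixes of
#' sorted ranks `i-1` and `i` (`lcp[0] = 0`), computed with Kasai's
#' algorithm.
#'
#' @inheritParams build_bwt
#' @return Integer vector of length `n`.
#' @export
build_lcp <- function(text, suffix_array) {
  n <- nchar(text)
  if (length(suffix_array) != n) stop("suffix array length mismatch")
  cpp_lcp_kasai(encode_dna(text), as.integer(suffix_array))
}

#' Build the document array
#'
#' For each BWT row (sorted suffix), the document containing the suffix's
#' starting position; the terminator suffix (position `n-1`) carries the
#' no-document sentinel `-1`.
#'
#' @param suffix_array Suffix array (0-based).
#' @param boundaries Data.frame of 0-based half-open intervals (`start`,
#'   `end`, `doc_id`) covering `[0, n-1)`, as produced by
#'   [concatenate_documents()].
#' @return Integer vector of document IDs, `-1` for the terminator row.
#' @export
build_document_array <- function(suffix_array, boundaries) {
  n <- length(suffix_array)
  if (n == 1L) return(-1L)
  b <- boundaries[order(boundaries$start), , drop = FALSE]
  if (n > 1L && (b$start[1L] != 0L || max(b$end) < n - 1L))
    stop("boundaries must cover [0, n-1)")
  idx <- findInterval(suffix_array, b$start)
  doc <- ifelse(suffix_array == n - 1L, -1L, b$doc_id[idx])
  if (any(is.na(doc)) ||
      any(doc != -1L & suffix_array >= b$end[pmax(idx, 1L)]))
    stop("offset outside all document boundaries")
  as.integer(doc)
}

#' Run-length encode a BWT
#'
#' Maximal equal-letter runs in row order.
#'
#' @param bwt BWT string.
#' @return Data.frame with one row per run: `run` (0-based index), `start`
#'   (0-based first BWT row), `length`, and `char`.
#' @examples
#' run_length_encode("G$CAAAA")  # runs G,$,C,A with lengths 1,1,1,4
#' @export
run_length_encode <- function(bwt) {
  if (!nzchar(bwt)) stop("empty BWT")
  chars <- strsplit(bwt, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  len <- as.integer(r$lengths)
  data.frame(run = seq_along(len) - 1L,
             start = cumsum(c(0L, len[-length(len)])),
             length = len,
             char = r$values,
             stringsAsFactors = FALSE)
}

#' Compute per-run repositioning thresholds
#'
#' For every run and every character `c` different from the run's character,
#' the threshold is the offset `t` in `[0, length]` such that offsets `< t`
#' reposition up and offsets `>= t` reposition down. Up/down is the
#' direction whose nearest `c`-carrying row has the larger range-minimum LCP
#' with the current row; ties break upward. `t = length` when `c` never
#' occurs below the run, `t = 0` when it never occurs above; `NA` marks a
#' character absent from the BWT (and the run's own character).
#'
#' @param runs Run table from [run_length_encode()].
#' @param lcp LCP array from [build_lcp()].
#' @param bwt BWT string.
#' @return Integer matrix (runs x 4) with columns `A`, `C`, `G`, `T`.
#' @export
compute_thresholds <- function(runs, lcp, bwt) {
  codes <- encode_dna(bwt)
  if (sum(runs$length) != length(codes)) stop("runs inconsistent with bwt")
  thr <- cpp_thresholds(codes, as.integer(lcp), runs$start, runs$length,
                        match(runs$char, .ALPHABET) - 1L)
  colnames(thr) <- c("A", "C", "G", "T")
  thr
}
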