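#' @useDynLib colorbwt, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal alphabet: $ = 0 < A = 1 < C = 2 < G = 3 < T = 4.
# '$' is the unique terminator and the lexicographically smallest symbol.
.ALPHABET <- c("$", "A", "C", "G", "T")

#' Encode a DNA string (plus terminator) as integer codes
#'
#' Maps the characters `$ A C G T` to the integer codes `0..4` used by the
#' low-level index machinery. Any other character raises an error.
#'
#' @param x A single character string over `$ACGT`.
#' @return An integer vector of codes, one per character.
#' @export
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  codes <- match(chars, .ALPHABET) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid characters in sequence: ", paste(bad, collapse = " "))
  }
  codes
}

#' Decode integer codes back to a DNA string
#'
#' @param codes Integer codes in `0..4` (see [encode_dna()]).
#' @return A single character string.
#' @export
decode_dna <- function(codes) {
  paste(.ALPHABET[codes + 1L], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x A single character string over `ACGT`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                               collapse = ""))
}

#' Sanitize reference sequences
#'
#' Upper-cases each sequence and splits it at every non-`ACGT` character
#' (ambiguity codes are removed, never replaced by invented bases), returning
#' the non-empty `ACGT` fragments.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return A list (one element per input sequence) of character vectors of
#'   clean fragments; a fragment-free sequence yields `character(0)`.
#' @export
sanitize_sequences <- function(seqs) {
  lapply(toupper(seqs), function(s) {
    frags <- strsplit(gsub("[^ACGT]+", "\n", s), "\n", fixed = TRUE)[[1L]]
    frags[nzchar(frags)]
  })
}
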