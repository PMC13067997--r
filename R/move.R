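#' Build the move table over the run-length encoded BWT
#'
#' One row per BWT run: the run character and length together with the LF
#' destination of the run head expressed as a (destination run `dest_run`,
#' offset `dest_offset`) pair. Stepping the table (see [lf_step()]) is
#' equivalent to rank-based LF-mapping on the uncompressed BWT.
#'
#' @param runs Run table from [run_length_encode()].
#' @param bwt BWT string (used for character counts).
#' @return The `runs` data.frame with extra integer columns `dest_run`,
#'   `dest_offset` and `lf_head` (global LF row of the run head).
#' @export
build_move_table <- function(runs, bwt) {
  codes <- encode_dna(bwt)
  if (sum(runs$length) != length(codes)) stop("runs inconsistent with bwt")
  counts <- tabulate(codes + 1L, nbins = 5L)
  mv <- cpp_move_table(runs$start, runs$length,
                       match(runs$char, .ALPHABET) - 1L, counts)
  runs$dest_run <- mv$dest_run
  runs$dest_offset <- mv$dest_offset
  runs$lf_head <- mv$lf_head
  runs
}

.pos_to_row <- function(move, pos) move$start[pos[1L] + 1L] + pos[2L]

#' One LF step on the move table
#'
#' Maps a position `(run i, offset j)` to the position of `LF(start_i + j)`:
#' the destination is `(dest_run_i, dest_offset_i + j)`, fast-forwarded
#' through subsequent runs while the offset exceeds the destination run
#' length.
#'
#' @param pos Integer vector `c(run, offset)`, 0-based.
#' @param move Move table from [build_move_table()] (or a built index's
#'   `$runs`).
#' @return Integer vector `c(run, offset)` of the LF destination.
#' @export
lf_step <- function(pos, move) {
  i <- pos[1L] + 1L
  if (i < 1L || i > nrow(move) || pos[2L] < 0L || pos[2L] >= move$length[i])
    stop("invalid move position")
  di <- move$dest_run[i] + 1L
  off <- move$dest_offset[i] + pos[2L]
  while (off >= move$length[di]) {
    off <- off - move$length[di]
    di <- di + 1L
  }
  c(di - 1L, off)
}

.reposition_cond <- function() {
  structure(class = c("cbwt_char_absent", "error", "condition"),
            list(message = "character absent from the index", call = NULL))
}

#' Reposition a move position onto a run of a given character
#'
#' Used on a case-2 mismatch during PML computation: moves to the last row
#' of the nearest run of `read_char` above (direction up) or the first row
#' of the nearest run below (down). The direction is chosen by `strategy`:
#' `"lcp_thresholds"` compares the offset to the stored LCP threshold,
#' `"mid_run"` goes up iff the offset is in the upper half of the run
#' (below `ceiling(length/2)`), `"always_up"` always goes up; all
#' strategies fall back to the only available direction when the character
#' does not occur on one side. A character absent from the index raises a
#' condition of class `cbwt_char_absent`.
#'
#' @param pos Integer vector `c(run, offset)`, 0-based.
#' @param read_char Single character in `ACGT`.
#' @param index A built index (see [build_index()]).
#' @param strategy One of `"lcp_thresholds"`, `"mid_run"`, `"always_up"`.
#' @return Integer vector `c(run, offset)` whose run carries `read_char`.
#' @export
reposition <- function(pos, read_char, index,
                       strategy = c("lcp_thresholds", "mid_run", "always_up")) {
  strategy <- match.arg(strategy)
  stopifnot(read_char %in% c("A", "C", "G", "T"))
  i <- pos[1L] + 1L
  j <- pos[2L]
  cc <- match(read_char, .ALPHABET) - 1L
  if (index$char_counts[[read_char]] == 0L) stop(.reposition_cond())
  if (index$runs$char[i] == read_char)
    stop("position already lies in a run of 'read_char'")
  upi <- index$nearest_up[i, cc]
  dni <- index$nearest_down[i, cc]
  go_up <- switch(strategy,
    lcp_thresholds = j < index$thresholds[i, cc],
    mid_run = {
      up <- j < ceiling(index$runs$length[i] / 2)
      if (up && upi < 0L) up <- FALSE
      if (!up && dni < 0L) up <- TRUE
      up
    },
    always_up = upi >= 0L
  )
  if (go_up) c(upi, index$runs$length[upi + 1L] - 1L) else c(dni, 0L)
}
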