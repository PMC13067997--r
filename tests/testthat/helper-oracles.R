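# Brute-force oracles, independent of the move-structure implementation:
# they work on the uncompressed text/BWT with naive sorting, rank-based LF
# and explicit range-minimum LCP scans.

oracle_sa <- function(text) {
  n <- nchar(text)
  sufs <- substring(text, 1:n)
  order(sufs, method = "radix") - 1L
}

oracle_lcp <- function(text, sa) {
  n <- nchar(text)
  sufs <- substring(text, sa + 1L)
  lcp <- integer(n)
  if (n > 1) {
    for (i in 2:n) {
      a <- sufs[i - 1L]; b <- sufs[i]
      k <- 0L
      while (k < nchar(a) && k < nchar(b) &&
             substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) k <- k + 1L
      lcp[i] <- k
    }
  }
  lcp
}

# rank-based LF as a permutation over 0-based rows, via stable sort of the
# BWT characters into the first column
oracle_lf <- function(bwt_chars) {
  ord <- order(bwt_chars, method = "radix")
  lf <- integer(length(bwt_chars))
  lf[ord] <- seq_along(bwt_chars) - 1L
  lf
}

# nearest rows above/below row x (0-based) carrying char c; -1 when none
oracle_nearest <- function(bwt_chars, x, c) {
  pos <- which(bwt_chars == c) - 1L
  up <- pos[pos < x]
  dn <- pos[pos > x]
  c(if (length(up)) max(up) else -1L, if (length(dn)) min(dn) else -1L)
}

# repositioning direction by brute-force range-minimum LCP; ties break up.
# Returns "up"/"down"/NA (char absent).
oracle_direction <- function(bwt_chars, lcp, x, c) {
  nb <- oracle_nearest(bwt_chars, x, c)
  u <- nb[1L]; d <- nb[2L]
  if (u < 0L && d < 0L) return(NA_character_)
  if (u < 0L) return("down")
  if (d < 0L) return("up")
  up_lcp <- min(lcp[(u + 2L):(x + 1L)])
  down_lcp <- min(lcp[(x + 2L):(d + 1L)])
  if (down_lcp > up_lcp) "down" else "up"
}

# Full PML + color-tally oracle on the uncompressed BWT. Returns the PML
# vector, per-document scores, and the 0-based BWT row visited at each
# position (-1 where the PML is 0).
oracle_pml <- function(text, read, strategy = "lcp_thresholds") {
  sa <- oracle_sa(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  bwt_chars <- chars[((sa - 1L) %% n) + 1L]
  lcp <- oracle_lcp(text, sa)
  lf <- oracle_lf(bwt_chars)
  rl <- rle(bwt_chars)
  run_of_row <- rep(seq_along(rl$lengths), rl$lengths)   # 1-based run ids
  run_start <- cumsum(c(0L, rl$lengths))[seq_along(rl$lengths)]
  rchars <- strsplit(toupper(read), "", fixed = TRUE)[[1L]]
  m <- length(rchars)
  pml <- integer(m)
  rows <- integer(m)
  row <- n - 1L
  len <- 0L
  for (k in m:1) {
    c <- rchars[k]
    if (!(c %in% c("A", "C", "G", "T")) || !any(bwt_chars == c)) {
      len <- 0L; pml[k] <- 0L; rows[k] <- -1L
      next
    }
    if (bwt_chars[row + 1L] == c) {
      len <- len + 1L
    } else {
      nb <- oracle_nearest(bwt_chars, row, c)
      ri <- run_of_row[row + 1L]
      off <- row - run_start[ri]
      go_up <- switch(strategy,
        lcp_thresholds = oracle_direction(bwt_chars, lcp, row, c) == "up",
        mid_run = {
          up <- off < ceiling(rl$lengths[ri] / 2)
          if (up && nb[1L] < 0L) up <- FALSE
          if (!up && nb[2L] < 0L) up <- TRUE
          up
        },
        always_up = nb[1L] >= 0L
      )
      row <- if (go_up) nb[1L] else nb[2L]
      len <- 0L
    }
    pml[k] <- len
    rows[k] <- if (len > 0L) row else -1L
    row <- lf[row + 1L]
  }
  list(pml = pml, rows = rows)
}

# matching statistic: longest prefix of read[k..] occurring in text
oracle_ms <- function(text, read) {
  m <- nchar(read)
  vapply(seq_len(m), function(k) {
    len <- 0L
    while (k + len <= m &&
           grepl(substr(read, k, k + len), text, fixed = TRUE)) len <- len + 1L
    len
  }, 0L)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small random document collection + built index (+ text for oracles)
random_case <- function(n_docs = NULL, len_range = c(20, 120),
                        strand = NULL) {
  if (is.null(n_docs)) n_docs <- sample(1:4, 1)
  if (is.null(strand))
    strand <- sample(c("forward_only", "with_reverse_complement"), 1)
  docs <- lapply(seq_len(n_docs), function(i)
    random_dna(sample(len_range[1]:len_range[2], 1)))
  names(docs) <- sprintf("D%d", seq_len(n_docs))
  coll <- reference_collection(docs)
  idx <- build_index(coll, strand_mode = strand)
  list(coll = coll, idx = idx, text = idx$structures$text, strand = strand)
}
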