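test_that("document concatenation follows ID order, strands and terminator", {
  coll <- reference_collection(list(D1 = "AAC", D2 = "AAG"))
  ct <- concatenate_documents(coll, "forward_only")
  expect_equal(ct$text, "AACAAG$")
  expect_equal(ct$n, 7L)
  expect_equal(ct$boundaries$start, c(0L, 3L))
  expect_equal(ct$boundaries$end, c(3L, 6L))
  expect_equal(ct$boundaries$doc_id, c(0L, 1L))

  ct1 <- concatenate_documents(reference_collection(list(D1 = "A")),
                               "forward_only")
  expect_equal(ct1$text, "A$")

  rc <- concatenate_documents(reference_collection(list(D1 = "AC")),
                              "with_reverse_complement")
  expect_equal(rc$text, "ACGT$")
  expect_true(all(rc$boundaries$doc_id == 0L))
})

test_that("sanitization splits at ambiguity codes and rejects empty docs", {
  coll <- reference_collection(list(D1 = c("acNNgt", "TT")))
  expect_equal(coll$sequences$D1, c("AC", "GT", "TT"))
  expect_error(reference_collection(list(D1 = "NNN")), "empty after")
  expect_error(reference_collection(list()), "non-empty")
})

test_that("suffix array, BWT and LCP match their definitions on fixed cases", {
  expect_equal(build_suffix_array("AACAAG$"), c(6L, 0L, 3L, 1L, 4L, 2L, 5L))
  expect_equal(build_suffix_array("ACG$"), c(3L, 0L, 1L, 2L))
  expect_equal(build_suffix_array("$"), 0L)
  expect_error(build_suffix_array("ACG"), "exactly one")
  expect_error(build_suffix_array("A$C$"), "exactly one")

  expect_equal(build_bwt("AACAAG$", c(6L, 0L, 3L, 1L, 4L, 2L, 5L)), "G$CAAAA")
  expect_equal(build_bwt("ACG$", c(3L, 0L, 1L, 2L)), "G$AC")
  expect_equal(build_bwt("A$", c(1L, 0L)), "A$")
  expect_error(build_bwt("ACG$", c(0L, 1L)), "mismatch")

  expect_equal(build_lcp("AACAAG$", build_suffix_array("AACAAG$")),
               c(0L, 0L, 2L, 1L, 1L, 0L, 0L))
  expect_equal(build_lcp("AAAA$", build_suffix_array("AAAA$")),
               c(0L, 0L, 1L, 2L, 3L))
  expect_equal(build_lcp("$", 0L), 0L)
})

test_that("document array resolves SA entries through boundaries", {
  sa <- build_suffix_array("AACAAG$")
  b <- data.frame(start = c(0L, 3L), end = c(3L, 6L), doc_id = c(0L, 1L))
  expect_equal(build_document_array(sa, b),
               c(-1L, 0L, 1L, 0L, 1L, 0L, 1L))
  # single document: all rows D0 except the terminator row
  sa1 <- build_suffix_array("ACG$")
  b1 <- data.frame(start = 0L, end = 3L, doc_id = 0L)
  expect_equal(build_document_array(sa1, b1), c(-1L, 0L, 0L, 0L))
  expect_equal(build_document_array(0L, b1[0, ]), -1L)
})

test_that("run-length encoding produces maximal runs summing to n", {
  runs <- run_length_encode("G$CAAAA")
  expect_equal(runs$char, c("G", "$", "C", "A"))
  expect_equal(runs$length, c(1L, 1L, 1L, 4L))
  expect_equal(runs$start, c(0L, 1L, 2L, 3L))
  expect_equal(nrow(run_length_encode("AAAA")), 1L)
  expect_equal(nrow(run_length_encode("ACGT")), 4L)
})

test_that("thresholds collapse to a single direction when one side is empty", {
  text <- "AACAAG$"
  sa <- build_suffix_array(text)
  bwt <- build_bwt(text, sa)
  thr <- compute_thresholds(run_length_encode(bwt), build_lcp(text, sa), bwt)
  # A-run rows 3-6: C and G only occur above -> t = run length (always up)
  expect_equal(thr[4, "C"], 4L, ignore_attr = TRUE)
  expect_equal(thr[4, "G"], 4L, ignore_attr = TRUE)
  # T absent from the BWT entirely
  expect_true(all(is.na(thr[, "T"])))
})

test_that("threshold ties break upward (both middle rows of CACG$ go up)", {
  text <- "CACG$"
  sa <- build_suffix_array(text)
  bwt <- build_bwt(text, sa)
  expect_equal(bwt, "GC$AC")
  runs <- run_length_encode(bwt)
  thr <- compute_thresholds(runs, build_lcp(text, sa), bwt)
  # rows 2 ($-run) and 3 (A-run) sit between the two C rows (1 and 4); the
  # up/down range-minimum LCPs tie at 0, so both rows reposition up
  expect_equal(thr[3, "C"], 1L, ignore_attr = TRUE)
  expect_equal(thr[4, "C"], 1L, ignore_attr = TRUE)
})

test_that("suffix structures match brute-force oracles on random collections", {
  set.seed(101)
  for (i in 1:25) {
    cs <- random_case()
    text <- cs$text
    sa <- cs$idx$structures$sa
    expect_identical(sa, oracle_sa(text))
    expect_identical(cs$idx$structures$lcp, oracle_lcp(text, sa))
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    n <- nchar(text)
    expect_identical(cs$idx$structures$bwt,
                     paste(chars[((sa - 1L) %% n) + 1L], collapse = ""))
  }
})

test_that("LF iteration from the terminator row reconstructs the text", {
  set.seed(202)
  for (i in 1:10) {
    cs <- random_case(len_range = c(10, 60))
    idx <- cs$idx
    n <- idx$meta$n
    bwt_chars <- strsplit(idx$structures$bwt, "", fixed = TRUE)[[1L]]
    # row 0 holds the terminator suffix; walking LF emits the text reversed
    pos <- c(0L, 0L)
    out <- character(n)
    for (k in 1:n) {
      row <- idx$runs$start[pos[1L] + 1L] + pos[2L]
      out[k] <- bwt_chars[row + 1L]
      pos <- lf_step(pos, idx$runs)
    }
    chars <- strsplit(cs$text, "", fixed = TRUE)[[1L]]
    expect_equal(paste(out, collapse = ""),
                 paste(c(chars[(n - 1):1], "$"), collapse = ""))
  }
})

test_that("runs get shorter relative to n as identical copies are added", {
  set.seed(303)
  base <- random_dna(300)
  nr_ratio <- vapply(c(1L, 4L, 8L), function(copies) {
    docs <- setNames(rep(list(base), copies), sprintf("D%d", 1:copies))
    idx <- build_index(reference_collection(docs),
                       strand_mode = "forward_only")
    idx$meta$n / idx$meta$r
  }, 0)
  expect_true(all(diff(nr_ratio) > 0))
})
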