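test_that("toy PML trace tallies both documents of the shared A-run", {
  idx <- toy_index()
  res <- query_read(idx, "AAG", strategy = "always_up")
  expect_equal(res$pml, c(2L, 1L, 0L))
  expect_equal(unname(res$scores), c(2L, 2L))
  expect_equal(names(res$scores), c("D1", "D2"))
})

test_that("reads made of characters absent from the index score nothing", {
  idx <- toy_index()  # no T in AACAAG$
  res <- query_read(idx, "TTTT")
  expect_equal(res$pml, rep(0L, 4))
  expect_true(all(res$scores == 0L))
  res2 <- query_read(idx, "NNN")
  expect_true(all(res2$pml == 0L))
  expect_error(query_read(idx, ""), "empty")
})

test_that("PML engine equals the uncompressed-BWT oracle for all strategies", {
  set.seed(707)
  for (i in 1:12) {
    cs <- random_case(len_range = c(20, 100))
    idx <- cs$idx
    for (rep_i in 1:4) {
      kind <- sample(c("substring", "mutated", "random"), 1)
      read <- switch(kind,
        substring = {
          doc <- sample(cs$coll$sequences, 1)[[1]][1]
          len <- min(nchar(doc), sample(10:40, 1))
          p <- sample(nchar(doc) - len + 1L, 1)
          substr(doc, p, p + len - 1L)
        },
        mutated = {
          doc <- sample(cs$coll$sequences, 1)[[1]][1]
          ch <- strsplit(doc, "")[[1]]
          hit <- which(runif(length(ch)) < 0.1)
          ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
          paste(ch, collapse = "")
        },
        random = random_dna(sample(10:50, 1))
      )
      for (s in c("lcp_thresholds", "mid_run", "always_up")) {
        impl <- query_read(idx, read, strategy = s, record = TRUE)
        orc <- oracle_pml(cs$text, read, strategy = s)
        expect_identical(impl$pml, orc$pml)
        # scores: tally brute-force run colors at the oracle's visited rows
        runs <- idx$runs
        run_of_row <- rep(seq_len(nrow(runs)), runs$length)
        want <- integer(idx$meta$n_docs)
        for (k in seq_along(orc$rows)) {
          if (orc$rows[k] < 0L) next
          col <- idx$colors[[runs$color_id[run_of_row[orc$rows[k] + 1L]] + 1L]]
          want[col + 1L] <- want[col + 1L] + 1L
        }
        expect_identical(unname(impl$scores), want)
      }
    }
  }
})

test_that("PMLs are sound substrings and under-approximate matching statistics", {
  set.seed(808)
  for (i in 1:8) {
    cs <- random_case(len_range = c(20, 80))
    idx <- cs$idx
    doc <- cs$coll$sequences[[1]][1]
    reads <- c(random_dna(40),
               substr(doc, 1, min(nchar(doc), 35)),
               paste0(random_dna(10), substr(doc, 1, 20)))
    text_body <- substr(cs$text, 1, idx$meta$n - 1L)
    ms_cache <- lapply(reads, oracle_ms, text = text_body)
    for (s in c("lcp_thresholds", "mid_run", "always_up")) {
      for (ri in seq_along(reads)) {
        read <- reads[ri]
        pml <- query_read(idx, read, strategy = s)$pml
        ms <- ms_cache[[ri]]
        expect_true(all(pml <= ms))
        sound <- vapply(which(pml > 0L), function(k)
          grepl(substr(read, k, k + pml[k] - 1L), text_body, fixed = TRUE),
          TRUE)
        expect_true(all(sound))
      }
    }
  }
})

test_that("within a case-1 streak some document is scored at every step", {
  set.seed(909)
  for (i in 1:8) {
    cs <- random_case(len_range = c(30, 90))
    idx <- cs$idx
    doc <- sample(cs$coll$sequences, 1)[[1]][1]
    read <- substr(doc, 1, min(nchar(doc), 50))
    res <- query_read(idx, read, record = TRUE)
    streak <- split(seq_along(res$pml)[res$pml > 0L],
                    cumsum(res$pml == 0L)[res$pml > 0L])
    for (ks in streak) {
      sets <- lapply(res$color_ids[ks] + 1L, function(ci) idx$colors[[ci]])
      expect_gt(length(Reduce(intersect, sets)), 0L)
    }
  }
})

test_that("average PML follows the arithmetic of the increment rule", {
  expect_equal(average_pml(c(2L, 1L, 0L)), 1)
  expect_equal(average_pml(rep(0L, 5)), 0)
  expect_error(average_pml(integer(0)), "at least 1")
  # a full-length match with no case-2 resets gives lengths m..1
  m <- 12L
  expect_equal(average_pml(rev(seq_len(m))), (m + 1) / 2)
})

test_that("cutoff calibration is the nearest-rank percentile", {
  expect_equal(calibrate_cutoff(rep(3.5, 10)), 3.5)
  expect_equal(calibrate_cutoff(sample(1:100), alpha = 0.05), 95)
  expect_equal(calibrate_cutoff(c(3, 1, 2), alpha = 0.5), 2)
  expect_error(calibrate_cutoff(numeric(0)), "empty")
  expect_error(calibrate_cutoff(1:10, alpha = 0), "alpha")
})

test_that("the binary gate is strictly above the cutoff", {
  expect_equal(binary_classify(10, 3), "in_index")
  expect_equal(binary_classify(3, 3), "unclassified")
  expect_equal(binary_classify(0, 0.5), "unclassified")
})

test_that("document reporting applies the runner-up ratio inclusively", {
  expect_equal(report_documents(c(2, 2)), c(0L, 1L))          # tie -> both
  expect_equal(report_documents(c(100, 94)), 0L)              # 94 < 95
  expect_equal(report_documents(c(100, 95)), c(0L, 1L))       # inclusive
  expect_equal(report_documents(c(0, 0)), integer(0))
  # max_extra caps the runner-ups in score order
  expect_equal(report_documents(c(10, 10, 10), max_extra = 1L), c(0L, 1L))
  expect_equal(report_documents(c(5, 9, 10), ratio = 0.5, max_extra = 2L),
               c(2L, 1L, 0L))
  expect_equal(report_documents(c(5, 9, 10), ratio = 0.5, max_extra = 1L),
               c(2L, 1L))
})

test_that("taxon assignment is the LCA of reported documents", {
  fx <- pangenome_fixture()
  idx <- fx$idx
  tax <- idx$taxonomy
  d0 <- idx$docs$doc_id[1]
  expect_equal(assign_taxon(d0, idx), idx$docs$taxon_id[1])
  # species 1 and 2 share genus_01; species 1 and 3 only share the root
  sp <- sort(unique(idx$docs$taxon_id))
  d_sp <- vapply(sp[1:3], function(t) idx$docs$doc_id[idx$docs$taxon_id == t][1], 0L)
  expect_equal(tax_rank(tax, assign_taxon(d_sp[1:2], idx)), "genus")
  expect_equal(assign_taxon(d_sp[c(1, 3)], idx), tax$root)
})

test_that("classify_read composes the gate, report and LCA", {
  fx <- pangenome_fixture()
  idx <- fx$idx
  set.seed(77)
  pos <- simulate_reads(fx$sim$held_out, fx$cfg, n_reads = 3L, seed = 991L)
  rec <- classify_read(idx, pos$reads[[1]], read_id = "r1", cutoff = 0.5)
  expect_equal(rec$status, "C")
  truth_sp <- pos$truth$taxon_id[1]
  # prediction is the true species or an ancestor of it
  expect_true(rec$taxon_id == truth_sp ||
              tax_is_ancestor(idx$taxonomy, rec$taxon_id, truth_sp))
  # a hopeless cutoff forces unclassified, but scores were still computed
  rec2 <- classify_read(idx, pos$reads[[2]], cutoff = Inf)
  expect_equal(rec2$status, "U")
  expect_true(is.na(rec2$taxon_id))
  expect_error(classify_read(idx, "ACGT"), "cutoff")
})
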