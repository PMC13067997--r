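.STRATEGIES <- c(lcp_thresholds = 0L, mid_run = 1L, always_up = 2L)

.read_codes <- function(read) {
  chars <- strsplit(toupper(read), "", fixed = TRUE)[[1L]]
  codes <- match(chars, .ALPHABET) - 1L
  codes[is.na(codes)] <- -1L  # non-ACGT read characters: never match
  codes
}

#' Compute pseudo-matching lengths with color tallying
#'
#' Processes the read right-to-left while tracking a single BWT offset,
#' starting from the position of `BWT[n-1]`. At each position the run
#' character either matches the read character (case 1: the length grows by
#' one) or not (case 2: the position is repositioned onto a run of the read
#' character per `strategy` and the length resets to 0). Whenever the fixed
#' length `L_k` is positive, the color of the current run is looked up and
#' every member document's score is incremented. Read characters absent
#' from the index give `L_k = 0` with no movement.
#'
#' @param index A built index ([build_index()] or [load_index()]).
#' @param read A nucleotide string (non-empty).
#' @param strategy Repositioning strategy: `"lcp_thresholds"` (default),
#'   `"mid_run"` or `"always_up"`.
#' @param record Also return per-position color IDs (`-1` where `L_k = 0`).
#' @return List with `pml` (integer vector `L_0..L_{m-1}`) and `scores`
#'   (integer vector of per-document scores, named by document name);
#'   with `record = TRUE` also `color_ids`.
#' @examples
#' idx <- build_index(reference_collection(list(D1 = "AAC", D2 = "AAG")),
#'                    strand_mode = "forward_only")
#' query_read(idx, "AAG", strategy = "always_up")$pml  # 2 1 0
#' @export
query_read <- function(index, read,
                       strategy = c("lcp_thresholds", "mid_run", "always_up"),
                       record = FALSE) {
  strategy <- match.arg(strategy)
  if (!nzchar(read)) stop("empty read")
  res <- cpp_query_pml(.read_codes(read), .STRATEGIES[[strategy]],
                       match(index$runs$char, .ALPHABET) - 1L,
                       index$runs$length, index$runs$dest_run,
                       index$runs$dest_offset, index$thresholds,
                       index$nearest_up, index$nearest_down,
                       index$runs$color_id, index$color_ptr, index$color_docs,
                       index$meta$n_docs, index$char_counts > 0L, record)
  names(res$scores) <- index$docs$name
  if (record) {
    res$color_ids <- res$pos_color
    res$pos_color <- NULL
  }
  res
}

#' Average pseudo-matching length of a read
#'
#' @param pml Integer vector of PMLs.
#' @param m Read length (defaults to `length(pml)`).
#' @return `sum(pml) / m`.
#' @export
average_pml <- function(pml, m = length(pml)) {
  if (m < 1L) stop("read length must be at least 1")
  sum(pml) / m
}

#' Calibrate the binary cutoff from null reads
#'
#' Nearest-rank `(1 - alpha)` percentile of the average PMLs of a null read
#' set (reads known not to originate from the index): the order statistic
#' of rank `ceiling((1 - alpha) * n)`.
#'
#' @param null_avgs Numeric vector of null average PMLs (non-empty).
#' @param alpha Allowed type-I error rate, in (0, 1); default 0.05.
#' @return The cutoff value.
#' @export
calibrate_cutoff <- function(null_avgs, alpha = 0.05) {
  if (length(null_avgs) == 0L) stop("empty null sample")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  sort(null_avgs)[ceiling((1 - alpha) * length(null_avgs))]
}

#' Binary in-index decision
#'
#' A read is called in-index iff its average PML is strictly above the
#' cutoff.
#'
#' @param avg Average PML of the read.
#' @param cutoff Calibrated cutoff (see [calibrate_cutoff()]).
#' @return `"in_index"` or `"unclassified"`.
#' @export
binary_classify <- function(avg, cutoff) {
  ifelse(avg > cutoff, "in_index", "unclassified")
}

#' Report the best-scoring documents
#'
#' The document with the highest score (`Dbest`; ties broken by smallest
#' document ID) followed by up to `max_extra` further documents whose score
#' is at least `ratio` times the best score (inclusive), in descending
#' score order.
#'
#' @param scores Integer vector of per-document scores, indexed by document
#'   ID `0..|D|-1`.
#' @param ratio Runner-up threshold as a fraction of the best score
#'   (default 0.95).
#' @param max_extra Maximum number of documents beyond `Dbest` (default 1).
#' @return Integer vector of document IDs; empty when all scores are zero.
#' @export
report_documents <- function(scores, ratio = 0.95, max_extra = 1L) {
  scores <- as.numeric(scores)
  best <- max(scores)
  if (best <= 0) return(integer(0))
  ids <- seq_along(scores) - 1L
  dbest <- ids[which(scores == best)[1L]]
  rest <- ids[ids != dbest & scores >= ratio * best & scores > 0]
  if (length(rest)) {
    rest <- rest[order(-scores[rest + 1L], rest)]
    rest <- utils::head(rest, max_extra)
  }
  c(dbest, rest)
}

#' Assign the taxon of a document report
#'
#' The lowest common ancestor of the reported documents' taxa; a single
#' document maps to its own taxon.
#'
#' @param doc_ids Integer vector of document IDs (non-empty).
#' @param index A built index with document-to-taxon mapping and taxonomy.
#' @return Taxonomy node ID.
#' @export
assign_taxon <- function(doc_ids, index) {
  if (length(doc_ids) == 0L) stop("empty document list")
  taxa <- index$docs$taxon_id[match(doc_ids, index$docs$doc_id)]
  if (anyNA(taxa)) stop("document without taxon mapping")
  if (is.null(index$taxonomy)) stop("index has no taxonomy")
  tax_lca(index$taxonomy, taxa)
}

#' Classify a single read
#'
#' Composes the query pipeline: PML computation with color tallying, average
#' PML, the binary in-index gate, document reporting, and LCA assignment.
#' Scores are always computed; the binary gate only sets the status. A read
#' with an all-zero score map is unclassified even if it passes the gate.
#'
#' @param index A built index with a taxonomy.
#' @param read Nucleotide string.
#' @param read_id Identifier used in reports.
#' @param strategy Repositioning strategy (see [query_read()]).
#' @param cutoff Binary cutoff; `NULL` uses the index's stored cutoff, and
#'   `NA` disables the binary gate.
#' @param ratio,max_extra Document-report parameters (see
#'   [report_documents()]).
#' @return A one-row data.frame: `read_id`, `status` (`"C"`/`"U"`),
#'   `taxon_id`, `taxon_rank`, `average_pml`, `reported_docs`
#'   (comma-separated document names), `top_scores` (comma-separated
#'   `name:score` of the reported documents).
#' @export
classify_read <- function(index, read, read_id = "read",
                          strategy = c("lcp_thresholds", "mid_run",
                                       "always_up"),
                          cutoff = NULL, ratio = 0.95, max_extra = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(cutoff)) cutoff <- index$cutoff
  if (is.null(cutoff))
    stop("no cutoff: calibrate one, pass one, or pass NA to disable the gate")
  res <- query_read(index, read, strategy)
  avg <- average_pml(res$pml, nchar(read))
  gate_ok <- is.na(cutoff) || avg > cutoff
  docs <- report_documents(res$scores, ratio, max_extra)
  if (!gate_ok || length(docs) == 0L) {
    return(data.frame(read_id = read_id, status = "U", taxon_id = NA_integer_,
                      taxon_rank = NA_character_, average_pml = avg,
                      reported_docs = "", top_scores = "",
                      stringsAsFactors = FALSE))
  }
  taxon <- assign_taxon(docs, index)
  nm <- index$docs$name[match(docs, index$docs$doc_id)]
  data.frame(read_id = read_id, status = "C", taxon_id = taxon,
             taxon_rank = tax_rank(index$taxonomy, taxon),
             average_pml = avg,
             reported_docs = paste(nm, collapse = ","),
             top_scores = paste(sprintf("%s:%d", nm,
                                        res$scores[match(docs,
                                                         index$docs$doc_id)]),
                                collapse = ","),
             stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' Applies [classify_read()] to each read independently; results are
#' identical to sequential processing by construction.
#'
#' @param index A built index with a taxonomy.
#' @param reads Named character vector of reads (names are read IDs).
#' @inheritParams classify_read
#' @return A data.frame with one row per read (see [classify_read()]).
#' @export
classify_reads <- function(index, reads,
                           strategy = c("lcp_thresholds", "mid_run",
                                        "always_up"),
                           cutoff = NULL, ratio = 0.95, max_extra = 1L) {
  strategy <- match.arg(strategy)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  out <- lapply(seq_along(reads), function(i) {
    classify_read(index, reads[[i]], ids[i], strategy, cutoff, ratio,
                  max_extra)
  })
  do.call(rbind, out)
}

#' Color fidelity of PML matches
#'
#' For every read position with `PML >= min_len`, compares the document set
#' implied by the tallied colors against the true set of documents
#' containing the exact match `R[k..k+L_k-1]` (the distinct documents over
#' the match's suffix-array interval). Two implied sets are evaluated:
#' `jaccard` uses the documents scored at every step of the current case-1
#' streak (the running intersection of the encountered colors — the set the
#' scoring scheme consistently credits for this match), and `jaccard_run`
#' uses the single current run's color. Requires an index built with
#' `keep_structures = TRUE`.
#'
#' @param index A built index retaining suffix structures.
#' @param reads Character vector of reads.
#' @param strategy Repositioning strategy.
#' @param min_len Minimum PML for which fidelity is evaluated (default 1).
#' @return Data.frame with columns `pml`, `jaccard` and `jaccard_run`, one
#'   row per evaluated read position.
#' @export
color_fidelity <- function(index, reads,
                           strategy = c("lcp_thresholds", "mid_run",
                                        "always_up"),
                           min_len = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(index$structures))
    stop("index was built without keep_structures = TRUE")
  run_char <- match(index$runs$char, .ALPHABET) - 1L
  out <- lapply(reads, function(rd) {
    res <- cpp_query_pml_fidelity(.read_codes(rd), .STRATEGIES[[strategy]],
                                  run_char, index$runs$length,
                                  index$runs$start, index$runs$dest_run,
                                  index$runs$dest_offset, index$thresholds,
                                  index$nearest_up, index$nearest_down,
                                  index$runs$color_id, index$color_ptr,
                                  index$color_docs, index$meta$n_docs,
                                  index$char_counts > 0L,
                                  index$structures$run_cum,
                                  index$structures$doc_array,
                                  as.integer(min_len))
    keep <- !is.na(res$jaccard)
    data.frame(pml = res$pml[keep], jaccard = res$jaccard[keep],
               jaccard_run = res$jaccard_run[keep])
  })
  do.call(rbind, out)
}

#' Calibrate and store a binary cutoff on an index
#'
#' Computes the average PML of each null read and stores the nearest-rank
#' `(1 - alpha)` percentile as the index's binary cutoff.
#'
#' @param index A built index.
#' @param null_reads Character vector of null reads (not from the index).
#' @param strategy Repositioning strategy.
#' @param alpha Type-I error rate (default 0.05).
#' @return The index with `$cutoff` set; the null average PMLs are attached
#'   as `attr(, "null_avgs")`.
#' @export
calibrate_index <- function(index, null_reads,
                            strategy = c("lcp_thresholds", "mid_run",
                                         "always_up"),
                            alpha = 0.05) {
  strategy <- match.arg(strategy)
  avgs <- vapply(null_reads, function(rd) {
    average_pml(query_read(index, rd, strategy)$pml, nchar(rd))
  }, 0)
  index$cutoff <- calibrate_cutoff(avgs, alpha)
  attr(index, "null_avgs") <- unname(avgs)
  index
}
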