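.CATEGORIES <- c("TP", "VP", "FP", "FPstar", "FN", "TN")

#' Categorize one read's classification at a taxonomic rank
#'
#' Six-way categorization of a (truth, prediction) pair at a fixed rank.
#' Both truth and prediction are lifted to their ancestors at the rank
#' before comparison; a prediction lying above the rank (no ancestor at the
#' rank) is a vague positive when it is an ancestor of the truth.
#'
#' * `TP`: prediction at the rank equals the truth at the rank.
#' * `VP`: prediction is a strict ancestor of the truth, above the rank.
#' * `FP`: read is from the index but classified to a wrong node at or
#'   above the rank (not an ancestor of the truth).
#' * `FPstar`: read is not from the index but was assigned a taxon.
#' * `FN`: read is from the index but reported unclassified.
#' * `TN`: read is not from the index and reported unclassified.
#'
#' Reads whose truth has no ancestor at the evaluated rank are excluded
#' (category `NA`).
#'
#' @param true_taxon Truth node ID, or `NA` when the read does not
#'   originate from the index.
#' @param pred_taxon Predicted node ID, or `NA` when unclassified.
#' @param rank Rank label at which to evaluate.
#' @param tax A [taxonomy()].
#' @return One of `"TP" "VP" "FP" "FPstar" "FN" "TN"`, or `NA`.
#' @export
categorize_read <- function(true_taxon, pred_taxon, rank, tax) {
  if (!(rank %in% tax$nodes$rank)) stop("rank unknown to taxonomy: ", rank)
  if (is.na(true_taxon)) {
    return(if (is.na(pred_taxon)) "TN" else "FPstar")
  }
  truth_at <- tax_ancestor_at_rank(tax, true_taxon, rank)
  if (is.na(truth_at)) return(NA_character_)  # no true label at this rank
  if (is.na(pred_taxon)) return("FN")
  pred_at <- tax_ancestor_at_rank(tax, pred_taxon, rank)
  if (!is.na(pred_at)) {
    if (pred_at == truth_at) "TP" else "FP"
  } else if (tax_is_ancestor(tax, pred_taxon, true_taxon)) {
    "VP"
  } else {
    "FP"
  }
}

#' Tally read categories at a rank
#'
#' @param true_taxa,pred_taxa Integer vectors (NA = not from index /
#'   unclassified), same length.
#' @param rank Rank label.
#' @param tax A [taxonomy()].
#' @return Named integer vector of counts over
#'   `TP, VP, FP, FPstar, FN, TN`; excluded reads are not counted.
#' @export
categorize_reads <- function(true_taxa, pred_taxa, rank, tax) {
  stopifnot(length(true_taxa) == length(pred_taxa))
  cats <- mapply(categorize_read, true_taxa, pred_taxa,
                 MoreArgs = list(rank = rank, tax = tax))
  table(factor(cats, levels = .CATEGORIES))
}

#' Micro-averaged rank-level PPV, sensitivity and F1
#'
#' `PPV = TP / (TP + FP + FP*)`, `sensitivity = TP / (TP + FP + FN + VP)`,
#' `F1` their harmonic mean. Vague positives lower sensitivity but never
#' PPV. Metrics with a zero denominator are `NA`.
#'
#' @param counts Named vector/list with entries `TP`, `VP`, `FP`, `FPstar`,
#'   `FN` (and optionally `TN`).
#' @return List with `ppv`, `sensitivity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$TP)
  vp <- as.numeric(counts$VP)
  fp <- as.numeric(counts$FP)
  fps <- as.numeric(counts$FPstar)
  fn <- as.numeric(counts$FN)
  ppv_den <- tp + fp + fps
  sen_den <- tp + fp + fn + vp
  ppv <- if (ppv_den > 0) tp / ppv_den else NA_real_
  sen <- if (sen_den > 0) tp / sen_den else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sen) && (ppv + sen) > 0)
    2 * ppv * sen / (ppv + sen) else NA_real_
  list(ppv = ppv, sensitivity = sen, f1 = f1)
}

#' Evaluate a classification report against a truth table
#'
#' Joins a per-read report to the truth by `read_id` and computes
#' category counts and metrics at each requested rank.
#'
#' @param report Data.frame as from [classify_reads()] (columns `read_id`,
#'   `taxon_id`; unclassified rows have `NA` taxon).
#' @param truth Data.frame with columns `read_id` and `taxon_id` (`NA` for
#'   reads not from the index).
#' @param tax A [taxonomy()].
#' @param ranks Character vector of rank labels.
#' @return Data.frame, one row per rank: the six counts, `ppv`,
#'   `sensitivity`, `f1`.
#' @export
evaluate_classifications <- function(report, truth, tax,
                                     ranks = c("species", "genus")) {
  m <- match(report$read_id, truth$read_id)
  if (anyNA(m)) stop("reads in report missing from truth table")
  true_taxa <- truth$taxon_id[m]
  rows <- lapply(ranks, function(rk) {
    cnt <- categorize_reads(true_taxa, report$taxon_id, rk, tax)
    met <- compute_metrics(cnt)
    cbind(data.frame(rank = rk), as.data.frame(t(as.matrix(cnt))),
          data.frame(ppv = met$ppv, sensitivity = met$sensitivity,
                     f1 = met$f1))
  })
  do.call(rbind, rows)
}
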