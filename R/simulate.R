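.BASES <- c("A", "C", "G", "T")

.random_genome <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# Substitution-only mutation at a fixed per-site rate; substituted sites get
# one of the three other bases uniformly.
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(chars, .BASES)
  hits <- which(stats::runif(length(codes)) < rate)
  if (length(hits)) {
    codes[hits] <- (codes[hits] - 1L +
                    sample.int(3L, length(hits), replace = TRUE)) %% 4L + 1L
  }
  paste(.BASES[codes], collapse = "")
}

#' Simulation configuration
#'
#' Defines a synthetic pangenome study: a shared ancestor is mutated into
#' per-species ancestors (inter-species divergence), each of which is
#' mutated into individual genomes (intra-species divergence). One genome
#' per species is held out for read simulation; the rest are indexed, each
#' as its own document. Defaults describe a desk-scale pangenome with
#' strong within-species redundancy and clear between-species divergence:
#' 10 species of 5 genomes (4 indexed + 1 held out) of 20 kb, 5% divergence
#' between species, 0.1% within, and error-free 2 kb reads.
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   simulations.
#' @param num_species Number of species.
#' @param genomes_per_species Genomes per species (one is held out).
#' @param genome_length Genome length in bases.
#' @param inter_divergence Per-site substitution rate from the common
#'   ancestor to each species ancestor.
#' @param intra_divergence Per-site substitution rate from a species
#'   ancestor to each of its genomes.
#' @param read_length_mean,read_length_sd Read length distribution
#'   (truncated normal; sd 0 gives fixed-length reads).
#' @param error_sub,error_ins,error_del Per-base read error rates.
#' @param num_null_genomes Number of genomes in the unrelated null clade
#'   (fresh random sequences sharing no ancestry with the index).
#' @param document_level `"species"` (default: all indexed genomes of a
#'   species form one document, the granularity the colored index uses for
#'   classification) or `"genome"` (each genome is its own document).
#' @return A list of class `cbwt_sim_config`.
#' @export
simulation_config <- function(seed = 1L, num_species = 10L,
                              genomes_per_species = 5L,
                              genome_length = 20000L,
                              inter_divergence = 0.05,
                              intra_divergence = 0.001,
                              read_length_mean = 2000L,
                              read_length_sd = 0L,
                              error_sub = 0, error_ins = 0, error_del = 0,
                              num_null_genomes = 3L,
                              document_level = c("species", "genome")) {
  document_level <- match.arg(document_level)
  cfg <- list(seed = as.integer(seed), num_species = as.integer(num_species),
              genomes_per_species = as.integer(genomes_per_species),
              genome_length = as.integer(genome_length),
              inter_divergence = inter_divergence,
              intra_divergence = intra_divergence,
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              error_sub = error_sub, error_ins = error_ins,
              error_del = error_del,
              num_null_genomes = as.integer(num_null_genomes),
              document_level = document_level)
  rates <- c(cfg$inter_divergence, cfg$intra_divergence, cfg$error_sub,
             cfg$error_ins, cfg$error_del)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  if (cfg$num_species < 1L || cfg$genomes_per_species < 2L ||
      cfg$genome_length < 10L || cfg$read_length_mean < 1)
    stop("degenerate simulation configuration")
  class(cfg) <- "cbwt_sim_config"
  cfg
}

#' Simulate a pangenome-like document collection
#'
#' Generates the reference side of a synthetic study: indexed documents, a
#' two-level taxonomy (species grouped pairwise into genera under a single
#' root), per-species held-out genomes for positive read simulation, and an
#' unrelated null clade. With `document_level = "species"` (the default,
#' matching how the colored index is typically deployed) the non-held-out
#' genomes of each species are grouped into one document; with `"genome"`
#' each genome is its own document. Deterministic under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `collection` (a [reference_collection()]),
#'   `taxonomy`, `held_out` (data.frame `name`, `seq`, `taxon_id`),
#'   `null_genomes` (same shape, `taxon_id = NA`), and `config`.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "cbwt_sim_config"))
  set.seed(config$seed)
  S <- config$num_species
  G <- config$genomes_per_species
  n_genera <- ceiling(S / 2)
  root_id <- 1L
  genus_ids <- root_id + seq_len(n_genera)
  species_ids <- root_id + n_genera + seq_len(S)
  tax <- taxonomy(data.frame(
    node_id = c(root_id, genus_ids, species_ids),
    parent_id = c(root_id, rep(root_id, n_genera),
                  genus_ids[ceiling(seq_len(S) / 2)]),
    rank = c("root", rep("genus", n_genera), rep("species", S)),
    name = c("root", sprintf("genus_%02d", seq_len(n_genera)),
             sprintf("species_%02d", seq_len(S))),
    stringsAsFactors = FALSE
  ))
  ancestor <- .random_genome(config$genome_length)
  docs <- list()
  taxa <- integer(0)
  held <- data.frame(name = character(0), seq = character(0),
                     taxon_id = integer(0), stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    sp_anc <- .mutate(ancestor, config$inter_divergence)
    genomes <- vapply(seq_len(G), function(g)
      .mutate(sp_anc, config$intra_divergence), "")
    held_idx <- sample.int(G, 1L)
    held <- rbind(held, data.frame(name = sprintf("sp%02d_g%d", s, held_idx),
                                   seq = genomes[held_idx],
                                   taxon_id = species_ids[s],
                                   stringsAsFactors = FALSE))
    kept <- setdiff(seq_len(G), held_idx)
    if (config$document_level == "species") {
      docs[[sprintf("species_%02d", s)]] <- genomes[kept]
      taxa <- c(taxa, species_ids[s])
    } else {
      for (g in kept) {
        docs[[sprintf("sp%02d_g%d", s, g)]] <- genomes[g]
        taxa <- c(taxa, species_ids[s])
      }
    }
  }
  null_genomes <- data.frame(
    name = sprintf("null_g%d", seq_len(config$num_null_genomes)),
    seq = vapply(seq_len(config$num_null_genomes), function(i)
      .random_genome(config$genome_length), ""),
    taxon_id = NA_integer_, stringsAsFactors = FALSE)
  list(collection = reference_collection(docs, taxon_id = taxa),
       taxonomy = tax, held_out = held, null_genomes = null_genomes,
       config = config)
}

.apply_read_errors <- function(seq, sub, ins, del) {
  if (sub <= 0 && ins <= 0 && del <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- length(chars)
  keep <- if (del > 0) stats::runif(m) >= del else rep(TRUE, m)
  codes <- match(chars, .BASES)
  if (sub > 0) {
    hits <- which(stats::runif(m) < sub & keep)
    if (length(hits))
      codes[hits] <- (codes[hits] - 1L +
                      sample.int(3L, length(hits), replace = TRUE)) %% 4L + 1L
  }
  out <- .BASES[codes[keep]]
  if (ins > 0) {
    k <- length(out)
    at <- which(stats::runif(k) < ins)
    if (length(at)) {
      extra <- sample(.BASES, length(at), replace = TRUE)
      pieces <- out
      pieces[at] <- paste0(pieces[at], extra)
      out <- pieces
    }
  }
  paste(out, collapse = "")
}

#' Simulate reads from a set of source genomes
#'
#' Draws reads uniformly over source genomes and start positions, samples a
#' strand when `strands = "both"`, and applies per-base substitution,
#' insertion and deletion errors at the configured rates. Positive reads
#' should be drawn from held-out genomes, null reads from the unrelated
#' null clade (`taxon_id = NA` in the truth table).
#'
#' @param sources Data.frame with columns `name`, `seq`, `taxon_id` (as
#'   returned in `simulate_pangenome()$held_out` / `$null_genomes`).
#' @param config A [simulation_config()] (read length and error rates).
#' @param n_reads Number of reads.
#' @param seed RNG seed for this read set.
#' @param strands `"both"` (default) or `"forward"`; use `"both"` when the
#'   index includes reverse complements.
#' @param prefix Read-ID prefix.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `taxon_id`, `source`).
#' @export
simulate_reads <- function(sources, config, n_reads, seed = config$seed + 1L,
                           strands = c("both", "forward"),
                           prefix = "read") {
  strands <- match.arg(strands)
  stopifnot(inherits(config, "cbwt_sim_config"), n_reads >= 1L)
  set.seed(seed)
  glen <- nchar(sources$seq)
  reads <- character(n_reads)
  ids <- sprintf("%s_%05d", prefix, seq_len(n_reads))
  taxa <- integer(n_reads)
  src <- character(n_reads)
  for (i in seq_len(n_reads)) {
    g <- sample.int(nrow(sources), 1L)
    len <- max(1L, round(stats::rnorm(1L, config$read_length_mean,
                                      config$read_length_sd)))
    if (len > glen[g]) stop("read longer than source genome")
    pos <- sample.int(glen[g] - len + 1L, 1L)
    rd <- substr(sources$seq[g], pos, pos + len - 1L)
    if (strands == "both" && stats::runif(1L) < 0.5)
      rd <- reverse_complement(rd)
    reads[i] <- .apply_read_errors(rd, config$error_sub, config$error_ins,
                                   config$error_del)
    taxa[i] <- sources$taxon_id[g]
    src[i] <- sources$name[g]
  }
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, taxon_id = taxa, source = src,
                          stringsAsFactors = FALSE))
}
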