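test_that("pangenome simulation is deterministic and holds out one genome per species", {
  cfg <- simulation_config(seed = 7L, num_species = 2L,
                           genomes_per_species = 3L, genome_length = 1000L,
                           read_length_mean = 200L,
                           document_level = "genome")
  sim1 <- simulate_pangenome(cfg)
  sim2 <- simulate_pangenome(cfg)
  expect_identical(sim1$collection$sequences, sim2$collection$sequences)
  expect_identical(sim1$held_out, sim2$held_out)
  expect_identical(sim1$null_genomes, sim2$null_genomes)
  expect_equal(nrow(sim1$collection$docs), 4L)  # (3 - 1) x 2 indexed
  expect_equal(nrow(sim1$held_out), 2L)
  # held-out genomes never appear among the indexed documents
  expect_false(any(sim1$held_out$seq %in% unlist(sim1$collection$sequences)))
  # two-level taxonomy: species under genera under a single root
  expect_equal(sort(unique(sim1$taxonomy$nodes$rank)),
               c("genus", "root", "species"))
  expect_true(all(sim1$collection$docs$taxon_id %in%
                  sim1$taxonomy$nodes$node_id))
  # species-level documents group the kept genomes of each species
  cfg_sp <- simulation_config(seed = 7L, num_species = 2L,
                              genomes_per_species = 3L,
                              genome_length = 1000L,
                              read_length_mean = 200L)
  sim_sp <- simulate_pangenome(cfg_sp)
  expect_equal(nrow(sim_sp$collection$docs), 2L)
  expect_equal(lengths(sim_sp$collection$sequences),
               c(species_01 = 2L, species_02 = 2L))
  expect_error(simulation_config(intra_divergence = 1.2), "rates")
  expect_error(simulation_config(genomes_per_species = 1L), "degenerate")
})

test_that("zero intra-species divergence yields identical genomes and higher n/r", {
  cfg0 <- simulation_config(seed = 9L, num_species = 2L,
                            genomes_per_species = 4L, genome_length = 600L,
                            intra_divergence = 0)
  sim <- simulate_pangenome(cfg0)
  for (g in sim$collection$sequences) expect_true(all(g == g[1]))
  # with all divergence off, every non-empty color is the full document set
  cfg00 <- simulation_config(seed = 9L, num_species = 2L,
                             genomes_per_species = 3L, genome_length = 300L,
                             intra_divergence = 0, inter_divergence = 0)
  idx <- build_index(simulate_pangenome(cfg00)$collection,
                     strand_mode = "forward_only")
  # identical documents: the full document set dominates the colors (only
  # runs near document junctions can carry a subset)
  full <- vapply(idx$colors, identical, TRUE, y = idx$docs$doc_id)
  covered <- sum(idx$runs$length[full[idx$runs$color_id + 1L]]) / idx$meta$n
  expect_gt(covered, 0.9)
})

test_that("read simulation is deterministic and respects error settings", {
  fx <- pangenome_fixture()
  r1 <- simulate_reads(fx$sim$held_out, fx$cfg, n_reads = 5L, seed = 123L)
  r2 <- simulate_reads(fx$sim$held_out, fx$cfg, n_reads = 5L, seed = 123L)
  expect_identical(r1, r2)
  expect_equal(unique(nchar(r1$reads)), fx$cfg$read_length_mean)
  expect_true(all(r1$truth$taxon_id %in% fx$sim$held_out$taxon_id))
  # error-free forward reads are exact substrings of their source genome
  r3 <- simulate_reads(fx$sim$held_out, fx$cfg, n_reads = 5L, seed = 5L,
                       strands = "forward")
  for (i in 1:5) {
    src <- fx$sim$held_out$seq[fx$sim$held_out$name == r3$truth$source[i]]
    expect_true(grepl(r3$reads[[i]], src, fixed = TRUE))
  }
  # a read longer than its source genome is an error
  expect_error(simulate_reads(fx$sim$held_out,
                              simulation_config(read_length_mean = 1e6),
                              n_reads = 1L, seed = 1L), "longer")
  # indel errors change read length on average
  noisy_cfg <- simulation_config(seed = 1L, error_del = 0.1,
                                 read_length_mean = 500L,
                                 genome_length = 5000L)
  held <- fx$sim$held_out
  noisy <- simulate_reads(held, noisy_cfg, n_reads = 10L, seed = 11L)
  expect_lt(mean(nchar(noisy$reads)), 500)
})

test_that("an exact substring of a repeat-free document attains the closed-form average", {
  # with a single random document every matched suffix has a unique
  # occurrence, so no case 2 can interrupt the streak: the lengths are
  # L..1 (or (L-1)..1, 0 if the arbitrary start row mismatches the last
  # base), giving an average of (L+1)/2 or (L-1)/2
  set.seed(55)
  doc <- random_dna(2000)
  idx <- build_index(reference_collection(list(D1 = doc)),
                     strand_mode = "forward_only")
  L <- 400L
  read <- substr(doc, 501, 500 + L)
  pml <- query_read(idx, read)$pml
  avg <- average_pml(pml)
  expect_lte(avg, (L + 1) / 2)
  expect_gte(avg, 0.9 * (L + 1) / 2)
  # resets can only happen while the match is short enough to be ambiguous;
  # once it is unique (~log4(n) bases) the streak runs to the read start
  expect_true(all(pml[seq_len(L - 25L)] > 0L))
})

test_that("positive average PMLs dominate null average PMLs", {
  fx <- pangenome_fixture()
  idx <- fx$idx
  pos <- simulate_reads(fx$sim$held_out, fx$cfg, n_reads = 15L, seed = 31L)
  nul <- simulate_reads(fx$sim$null_genomes, fx$cfg, n_reads = 15L,
                        seed = 32L)
  avg <- function(rds) vapply(rds, function(r)
    average_pml(query_read(idx, r)$pml), 0)
  expect_gt(min(avg(pos$reads)), max(avg(nul$reads)))
})
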