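# Shared desk-scale pangenome fixture, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

pangenome_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- simulation_config(seed = 42L)  # 10 sp x 5 genomes x 20 kb, 2 kb reads
    sim <- simulate_pangenome(cfg)
    idx <- build_index(sim$collection, taxonomy = sim$taxonomy,
                       strand_mode = "with_reverse_complement")
    .fixture_env$fx <- list(cfg = cfg, sim = sim, idx = idx)
  }
  .fixture_env$fx
}

# tiny two-document index used by several frozen-example tests
toy_index <- function(strand = "forward_only") {
  build_index(reference_collection(list(D1 = "AAC", D2 = "AAG")),
              strand_mode = strand)
}
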