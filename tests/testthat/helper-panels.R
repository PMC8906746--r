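# Shared simulated panels, built once per test run and memoized.

.panel_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .panel_cache)) {
    assign(key, builder(), envir = .panel_cache)
  }
  get(key, envir = .panel_cache)
}

# Small constant-size single-population panel (2 x 1 Mb, 20 diploids).
single_pop_panel <- function(seed = 21) {
  cached(paste0("single", seed), function() {
    simulate_panel(
      demography_model(c(pop = 10000)),
      sim_params(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6), seed = seed),
      c(pop = 20))
  })
}

# Five-species panel on a 4 x 2 Mb genome: the default study scenario.
species_panel <- function(seed = 7) {
  cached(paste0("species", seed), function() {
    simulate_panel(
      default_scenario(),
      sim_params(chrom_lengths = stats::setNames(rep(2e6, 4),
                                                 paste0("chr", 1:4)),
                 seed = seed),
      c(ornamental = 10, splendens = 4, imbellis = 4, mahachaiensis = 4,
        outgroup = 2))
  })
}

# Hand-built panel from a haplotype matrix (rows = haplotypes, 2 per sample).
toy_panel <- function(haps, pos, len = max(pos) + 100,
                      pops = rep("g", nrow(haps) / 2)) {
  storage.mode(haps) <- "integer"
  haplotype_panel(paste0("s", seq_len(nrow(haps) / 2)), pops,
                  list(chr1 = list(positions = as.integer(pos),
                                   haplotypes = haps)),
                  c(chr1 = len))
}
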