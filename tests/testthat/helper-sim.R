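# small study configuration used across tests: two 150 kb euchromatic
# chromosomes, a 40 kb heterochromatin block, a 20 kb chr4-like chromosome,
# two TE families, nine planted insertions, 25x WGS of 100 bp pairs
tiny_cfg <- function(master_seed = 1L, ...) {
  args <- list(
    master_seed = master_seed,
    chrom_specs = tibble::tibble(
      name = c("chrA", "chrB", "chrHet", "chr4"),
      length = c(150000L, 150000L, 40000L, 20000L),
      class = c("euchromatin", "euchromatin",
                "heterochromatin_block", "chr4_like")),
    te_families = tibble::tibble(
      name = c("roo", "copia"),
      length = c(1200L, 900L),
      gc = c(0.45, 0.42)),
    n_insertions = c(roo = 6L, copia = 3L),
    wgs = list(fragment_mean = 300, fragment_sd = 30,
               read_length = 100L, coverage = 25),
    smallrna = list(
      family_fractions = c(roo = 0.6, copia = 0.4),
      antisense_fraction = 0.8,
      length_probs = NULL,
      adapter = "AGATCGGAAGAGCACACGTCT"))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# genome + indexes, cached per seed within a test run
tiny_bundle_cache <- new.env(parent = emptyenv())
tiny_bundle <- function(master_seed = 1L) {
  key <- as.character(master_seed)
  if (is.null(tiny_bundle_cache[[key]])) {
    cfg <- tiny_cfg(master_seed)
    genome <- build_genome(cfg)
    tiny_bundle_cache[[key]] <- list(
      cfg = cfg, genome = genome,
      te_idx = build_index(genome$te_seqs, k = 21),
      gen_idx = build_index(genome$reference, k = 21))
  }
  tiny_bundle_cache[[key]]
}

# independent Benjamini-Hochberg implementation (oracle for padj checks)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# GC fraction of a DNA string
gc_fraction <- function(s) {
  tab <- table(strsplit(s, "", fixed = TRUE)[[1]])
  sum(tab[c("G", "C")], na.rm = TRUE) / nchar(s)
}
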