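test_that("zero insertions give identical genomes and an empty truth table", {
  cfg <- tiny_cfg(3L, n_insertions = c(roo = 0L, copia = 0L))
  g <- build_genome(cfg)
  expect_identical(g$reference, g$sample)
  expect_equal(nrow(g$insertions), 0L)
})

test_that("genome building is byte-identical under a fixed seed", {
  g1 <- build_genome(tiny_cfg(7L))
  g2 <- build_genome(tiny_cfg(7L))
  expect_identical(g1$reference, g2$reference)
  expect_identical(g1$sample, g2$sample)
  expect_identical(g1$insertions, g2$insertions)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$sample, f1); write_fasta(g2$sample, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reference GC recovers the configured fraction (binomial band)", {
  cfg <- sim_config(
    master_seed = 11L,
    chrom_specs = tibble::tibble(name = "chrG", length = 500000L,
                                 class = "euchromatin"),
    n_insertions = c(roo = 0L, copia = 0L, TE297 = 0L),
    genome_gc = 0.40)
  g <- build_genome(cfg)
  obs <- gc_fraction(g$reference[["chrG"]])
  band <- 3 * sqrt(0.40 * 0.60 / 500000)
  expect_lt(abs(obs - 0.40), band)
})

test_that("planted insertions sit in euchromatin and splice the consensus", {
  b <- tiny_bundle(1L)
  g <- b$genome
  eu <- g$regions$chrom[g$regions$class == "euchromatin"]
  expect_true(all(g$insertions$chrom %in% eu))
  # spliced copy present in sample, absent from reference
  for (i in seq_len(nrow(g$insertions))) {
    ins <- g$insertions[i, ]
    te <- g$te_seqs[[ins$family]]
    if (ins$strand == "-") te <- revcomp(te)
    spliced <- substr(g$sample[[ins$chrom]], ins$sample_start + 1L,
                      ins$sample_end)
    expect_identical(spliced, te)
  }
  expect_false(grepl(g$te_seqs[["roo"]], g$reference[["chrA"]], fixed = TRUE))
})

test_that("infeasible insertion demand raises a configuration error", {
  expect_error(
    build_genome(tiny_cfg(1L, n_insertions = c(roo = 500L, copia = 0L))),
    "cannot place")
})

test_that("RNA-seq truth tags conserve read counts and family fractions", {
  b <- tiny_bundle(1L)
  tp <- "4-6h"
  rna <- simulate_rnaseq(b$genome, b$cfg, tp, 50000, seed = 5)
  expect_equal(nrow(rna$truth), 50000L)
  expect_equal(nrow(rna$reads), 50000L)
  expect_identical(rna$reads$read_id, rna$truth$read_id)
  # binomial oracle on the dominant-family tag count
  frac <- with(b$cfg$expression_profile,
               fraction[family == "roo" & timepoint == tp])
  n_roo <- sum(rna$truth$origin == "TE" & rna$truth$target == "roo")
  band <- 3 * sqrt(frac * (1 - frac) * 50000)
  expect_lt(abs(n_roo - frac * 50000), band)
  # reads are exact substrings of their stated origin (error-free config)
  i <- which(rna$truth$origin == "TE")[1]
  expect_identical(
    substr(b$genome$te_seqs[[rna$truth$target[i]]],
           rna$truth$position[i] + 1L, rna$truth$position[i] + 75L),
    rna$reads$seq[i])
})

test_that("zero TE expression yields no TE-tagged reads", {
  cfg <- tiny_cfg(2L)
  cfg$expression_profile$fraction <- 0
  g <- build_genome(cfg)
  rna <- simulate_rnaseq(g, cfg, "4-6h", 2000, seed = 1)
  expect_equal(sum(rna$truth$origin == "TE"), 0L)
  expect_error(simulate_rnaseq(g, cfg, "4-6h", 0), "n_reads")
  expect_error(simulate_rnaseq(g, cfg, "not-a-tp", 100), "timepoint")
})

test_that("WGS pair count, fragment length and FR geometry match the model", {
  b <- tiny_bundle(1L)
  wgs <- simulate_wgs(b$genome, b$cfg, seed = 9)
  lam <- b$cfg$wgs$coverage * sum(nchar(b$genome$sample)) /
    (2 * b$cfg$wgs$read_length)
  expect_lt(abs(nrow(wgs$truth) - lam), 3 * sqrt(lam))
  mf <- mean(wgs$truth$fragment_length)
  se <- b$cfg$wgs$fragment_sd / sqrt(nrow(wgs$truth))
  expect_lt(abs(mf - b$cfg$wgs$fragment_mean), 3 * se + 0.5)
  # FR orientation: mate1 = fragment prefix, mate2 = revcomp of suffix
  fr <- wgs$truth[1, ]
  chromseq <- b$genome$sample[[fr$chrom]]
  rl <- b$cfg$wgs$read_length
  m1 <- wgs$reads$seq[wgs$reads$read_id == fr$read_id & wgs$reads$mate == 1]
  m2 <- wgs$reads$seq[wgs$reads$read_id == fr$read_id & wgs$reads$mate == 2]
  expect_identical(m1, substr(chromseq, fr$start + 1L, fr$start + rl))
  expect_identical(
    m2, revcomp(substr(chromseq, fr$start + fr$fragment_length - rl + 1L,
                       fr$start + fr$fragment_length)))
  # zero coverage -> empty library
  cfg0 <- tiny_cfg(1L)
  cfg0$wgs$coverage <- 0
  empty <- simulate_wgs(b$genome, cfg0, seed = 1)
  expect_equal(nrow(empty$reads), 0L)
})

test_that("ChIP kernel weight grid honours E0 = 1, lag = 0 and skew = 1", {
  b <- tiny_bundle(1L)
  cfg_flat <- b$cfg
  cfg_flat$chip_kernel$E0 <- 1
  w <- burstchrom:::chip_weight_grid(b$genome, cfg_flat, lagv = 1)
  expect_true(all(w[["chrA"]] == 1))
  w0 <- burstchrom:::chip_weight_grid(b$genome, b$cfg, lagv = 0)
  expect_true(all(w0[["chrA"]] == 1))
  # symmetric kernel when skew = 1, for one isolated + insertion
  cfg_sym <- tiny_cfg(1L, n_insertions = c(roo = 1L, copia = 0L))
  cfg_sym$chip_kernel$skew <- 1
  g1 <- build_genome(cfg_sym)
  ws <- burstchrom:::chip_weight_grid(g1, cfg_sym, lagv = 1)
  ins <- g1$insertions[1, ]
  gres <- 25L
  v <- ws[[ins$chrom]]
  i_lo <- floor(ins$sample_start / gres)  # bin left of the element start
  i_hi <- ceiling(ins$sample_end / gres) + 1L
  off <- 1:40
  left <- v[i_lo - off]
  right <- v[i_hi + off]
  expect_lt(max(abs(left - right)), 0.15 * max(left))
})

test_that("ChIP IP coverage is flat near insertions when E0 = 1", {
  cfg <- tiny_cfg(4L)
  cfg$chip_kernel$E0 <- 1
  g <- build_genome(cfg)
  chip <- simulate_chip(g, cfg, "6-8h", 40000, 40000, seed = 3)
  ipr <- dplyr::filter(chip$truth, library == "ip")
  # within a chromosome class the density is uniform when E0 = 1, so compare
  # near-insertion counts to the per-chromosome uniform expectation
  near <- 0; expected <- 0
  for (i in seq_len(nrow(g$insertions))) {
    ins <- g$insertions[i, ]
    on_chrom <- ipr$chrom == ins$chrom
    near <- near + sum(on_chrom &
                         abs(ipr$position - ins$sample_start) < 1000)
    expected <- expected + sum(on_chrom) * 2000 / nchar(g$sample[[ins$chrom]])
  }
  expect_lt(abs(near - expected), 3 * sqrt(expected) + 1)
  expect_error(simulate_chip(g, cfg, "no-tp", 10, 10), "lag map")
})

test_that("small RNA reads carry linkers, adapter and configured fractions", {
  b <- tiny_bundle(1L)
  cfg <- b$cfg
  sr <- simulate_smallrna(b$genome, cfg, 30000, seed = 6)
  expect_equal(nrow(sr$reads), 30000L)
  # structure: 4 nt + insert + 4 nt + adapter
  expect_identical(
    substr(sr$reads$seq[1], 5L, 4L + sr$truth$insert_length[1]),
    sr$truth$insert[1])
  expect_true(all(endsWith(sr$reads$seq, cfg$smallrna$adapter)))
  # lengths inside the configured support
  expect_true(all(sr$truth$insert_length >= 19 & sr$truth$insert_length <= 31))
  # multinomial oracle on family proportions
  obs <- table(factor(sr$truth$family, levels = names(cfg$smallrna$family_fractions)))
  exp_p <- cfg$smallrna$family_fractions
  for (f in names(exp_p)) {
    band <- 3 * sqrt(exp_p[[f]] * (1 - exp_p[[f]]) * 30000)
    expect_lt(abs(obs[[f]] - exp_p[[f]] * 30000), band)
  }
  # antisense fraction binomial oracle
  n_anti <- sum(sr$truth$orientation == "antisense")
  band <- 3 * sqrt(0.8 * 0.2 * 30000)
  expect_lt(abs(n_anti - 0.8 * 30000), band)
  # degenerate antisense fraction
  cfg1 <- tiny_cfg(1L)
  cfg1$smallrna$antisense_fraction <- 1
  sr1 <- simulate_smallrna(b$genome, cfg1, 500, seed = 2)
  expect_true(all(sr1$truth$orientation == "antisense"))
})

test_that("each simulator is deterministic given config and seed", {
  b <- tiny_bundle(1L)
  expect_identical(simulate_rnaseq(b$genome, b$cfg, "4-6h", 500, seed = 3),
                   simulate_rnaseq(b$genome, b$cfg, "4-6h", 500, seed = 3))
  expect_identical(simulate_wgs(b$genome, b$cfg, seed = 4)$reads[1:50, ],
                   simulate_wgs(b$genome, b$cfg, seed = 4)$reads[1:50, ])
  expect_identical(simulate_smallrna(b$genome, b$cfg, 200, seed = 5),
                   simulate_smallrna(b$genome, b$cfg, 200, seed = 5))
  expect_false(identical(
    simulate_rnaseq(b$genome, b$cfg, "4-6h", 500, seed = 3)$reads$seq,
    simulate_rnaseq(b$genome, b$cfg, "4-6h", 500, seed = 4)$reads$seq))
})

test_that("config invariants are enforced", {
  expect_error(tiny_cfg(1L, genome_gc = 1.2), "GC")
  expect_error(tiny_cfg(1L, strand_prob = 0.5,
                        chip_kernel = list(E0 = 0.5, lambda = 100, skew = 1,
                                           lag = c("4-6h" = 1),
                                           het_fold = 2, chr4_fold = 2)),
               "E0")
  ep_bad <- tibble::tibble(family = c("roo", "copia"),
                           timepoint = "t", fraction = c(0.7, 0.6))
  expect_error(tiny_cfg(1L, expression_profile = ep_bad), "sum")
  expect_error(tiny_cfg(1L, wgs = list(fragment_mean = 90, fragment_sd = 5,
                                       read_length = 100L, coverage = 1)),
               "fragment")
})
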