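test_that("index covers L - k + 1 forward seeds and rejects bad input", {
  s <- c(seqX = paste(rep("ACGTA", 20), collapse = ""))  # 100 bp
  idx <- build_index(s, k = 15)
  expect_equal(sum(idx$dt$oid == 1), 86L)    # forward seeds
  expect_equal(nrow(idx$dt), 2L * 86L)       # both strands
  expect_error(build_index(s, k = 9), "k must be")
  expect_error(build_index(c(a = "ACGT", a = "ACGT"), k = 11), "unique")
  expect_error(build_index(character(0)), "non-empty")
})

test_that("a query equal to an indexed sequence hits once, revcomp flips strand", {
  set.seed(1)
  s <- setNames(random_dna(300, 0.45), "tgt")
  idx <- build_index(s, k = 21)
  q <- substr(s[["tgt"]], 51, 150)
  a <- assign_reads(tibble::tibble(read_id = "r1", seq = q), te_index = idx)
  expect_equal(a$category, "TE")
  expect_equal(a$target, "tgt")
  expect_equal(a$pos, 50L)
  expect_equal(a$strand, "+")
  expect_equal(a$n_candidates, 1L)
  expect_true(a$unique)
  arc <- assign_reads(tibble::tibble(read_id = "r1", seq = revcomp(q)),
                      te_index = idx)
  expect_equal(arc$pos, 50L)
  expect_equal(arc$strand, "-")
})

test_that("multimapper allocation is uniform across tied families", {
  set.seed(2)
  shared <- random_dna(120, 0.5)
  te <- c(famA = paste0(random_dna(200, 0.5), shared),
          famB = paste0(shared, random_dna(200, 0.5)))
  idx <- build_index(te, k = 21)
  n <- 5000
  reads <- tibble::tibble(read_id = paste0("r", 1:n),
                          seq = rep(substr(shared, 11, 110), n))
  a <- assign_reads(reads, te_index = idx, seed = 99)
  expect_true(all(a$category == "TE"))
  expect_true(all(a$n_candidates == 2L))
  expect_false(any(a$unique))
  fA <- sum(a$target == "famA")
  expect_lt(abs(fA - n / 2), 3 * sqrt(0.25 * n))
  # changing the seed changes only the allocations
  a2 <- assign_reads(reads, te_index = idx, seed = 100)
  expect_identical(a$category, a2$category)
  expect_false(identical(a$target, a2$target))
})

test_that("genome multimappers are discarded, unique loci kept (tier 2/3)", {
  set.seed(3)
  dup <- random_dna(200, 0.5)
  gen <- c(chr1 = paste0(random_dna(500, 0.5), dup, random_dna(500, 0.5)),
           chr2 = paste0(random_dna(300, 0.5), dup))
  gi <- build_index(gen, k = 21)
  reads <- tibble::tibble(
    read_id = c("amb", "uni"),
    seq = c(substr(dup, 41, 140), substr(gen[["chr1"]], 101, 200)))
  a <- assign_reads(reads, genome_index = gi)
  expect_equal(a$category, c("UNMAPPED", "GENOME"))
  expect_equal(a$n_candidates, c(2L, 1L))
  expect_equal(a$pos[2], 100L)
  expect_true(is.na(a$target[1]))
})

test_that("tier order is absolute: TE hits pre-empt genome hits", {
  set.seed(4)
  te_seq <- random_dna(400, 0.45)
  gen <- c(chr1 = paste0(random_dna(300, 0.5), te_seq, random_dna(300, 0.5)))
  ti <- build_index(c(roo = te_seq), k = 21)
  gi <- build_index(gen, k = 21)
  reads <- tibble::tibble(read_id = "r1", seq = substr(te_seq, 101, 200))
  a <- assign_reads(reads, ti, gi)
  expect_equal(a$category, "TE")
  expect_equal(a$target, "roo")
})

test_that("no GENOME-assigned read retains any TE-consensus hit", {
  b <- tiny_bundle(1L)
  rna <- simulate_rnaseq(b$genome, b$cfg, "4-6h", 3000, seed = 8)
  a <- assign_reads(rna$reads, b$te_idx, b$gen_idx, seed = 1)
  gidx <- which(a$category == "GENOME")[1:200]
  cand <- burstchrom:::index_candidates(b$te_idx, rna$reads$seq[gidx], 2L)
  expect_equal(nrow(cand), 0L)
})

test_that("assignment reproduces simulation truth on error-free reads", {
  b <- tiny_bundle(1L)
  rna <- simulate_rnaseq(b$genome, b$cfg, "4-6h", 8000, seed = 12)
  a <- assign_reads(rna$reads, b$te_idx, b$gen_idx, seed = 1)
  m <- dplyr::inner_join(a, rna$truth, by = "read_id",
                         suffix = c("", ".truth"))
  te <- m[m$origin == "TE", ]
  expect_true(all(te$category == "TE"))
  expect_true(all(te$target == te$target.truth))
  gen <- m[m$category == "GENOME", ]
  expect_true(all(gen$target == gen$target.truth &
                    gen$pos == gen$position &
                    gen$strand == gen$strand.truth))
  # per-family counts equal the truth-table recount
  cf <- count_features(a)
  truth_counts <- table(rna$truth$target[rna$truth$origin == "TE"])
  for (f in names(truth_counts)) {
    expect_equal(cf$count[cf$feature == f], unname(truth_counts[[f]]))
  }
})

test_that("count tables conserve totals and rpm mass", {
  b <- tiny_bundle(1L)
  rna <- simulate_rnaseq(b$genome, b$cfg, "4-6h", 4000, seed = 13)
  a <- assign_reads(rna$reads, b$te_idx, b$gen_idx, seed = 1)
  cf <- count_features(a)
  expect_equal(sum(cf$count[cf$category == "TE"]),
               sum(a$category == "TE"))
  expect_equal(attr(cf, "library_total"), sum(a$category != "UNMAPPED"))
  rpm <- rpm_normalize(cf)
  expect_equal(sum(rpm$rpm), 1e6)  # features partition all assigned reads
  # empty input
  cf0 <- count_features(a[0, ], features = c("roo", "copia"))
  expect_equal(cf0$count, c(0L, 0L))
  expect_equal(attr(cf0, "library_total"), 0L)
  expect_error(rpm_normalize(cf0), "library_total")
  # scaling factor is a plain ratio
  expect_equal(scaling_factor(500, 1000), 0.5)
  expect_error(scaling_factor(1, 0), "library_total")
})

test_that("rpm definition matches the 1.7%-of-transcriptome identity", {
  counts <- tibble::tibble(feature = "roo", category = "TE", count = 17000L)
  attr(counts, "library_total") <- 1e6
  rpm <- rpm_normalize(counts)
  expect_equal(rpm$rpm, 17000)
  tc <- te_fraction_timecourse(
    list(tp = rpm))
  expect_equal(tc$total$te_pct, 1.7)
})

test_that("timecourse percentages are additive and zero-safe", {
  mk <- function(roo, copia, genome) {
    x <- tibble::tibble(feature = c("roo", "copia", "chr1"),
                        category = c("TE", "TE", "GENOME"),
                        count = c(roo, copia, genome))
    attr(x, "library_total") <- roo + copia + genome
    rpm_normalize(x)
  }
  tc <- te_fraction_timecourse(list(t1 = mk(100, 50, 9850),
                                    t2 = mk(340, 60, 19600)))
  by_fam_sum <- tc$by_family |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(s = sum(pct))
  expect_equal(by_fam_sum$s,
               tc$total$te_pct[match(by_fam_sum$timepoint,
                                     tc$total$timepoint)])
  zero <- tibble::tibble(feature = "chr1", category = "GENOME", count = 100L)
  attr(zero, "library_total") <- 100L
  tc0 <- te_fraction_timecourse(list(t1 = rpm_normalize(zero)))
  expect_equal(tc0$total$te_pct, 0)
})

test_that("assignment is deterministic and stable across repeated calls", {
  b <- tiny_bundle(1L)
  rna <- simulate_rnaseq(b$genome, b$cfg, "4-6h", 1000, seed = 21)
  a1 <- assign_reads(rna$reads, b$te_idx, b$gen_idx, seed = 7)
  a2 <- assign_reads(rna$reads, b$te_idx, b$gen_idx, seed = 7)
  expect_identical(a1, a2)
})
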