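# hand-built genome assignments: uniform single-chromosome reads
mk_genome_asn <- function(pos, chrom = "chr1", len = 50L) {
  tibble::tibble(
    read_id = paste0("r", seq_along(pos)), mate = NA_integer_,
    category = "GENOME", target = chrom, pos = as.integer(pos),
    strand = "+", len = len, unique = TRUE, n_candidates = 1L,
    mismatches = 0L)
}

test_that("coverage tracks conserve read mass and handle empty input", {
  lens <- c(chr1 = 10000L)
  a <- mk_genome_asn(c(0L, 95L, 9990L), len = 50L)
  expect_warning(tr <- coverage_track(a, lens, bin_size = 10),
                 "clipped")
  mass <- sum(unlist(tr$values)) * tr$bin_size * tr$library_total / 1e6
  expect_equal(mass, 50 + 50 + 10)  # last read clipped at chromosome end
  tr0 <- coverage_track(a[0, ], lens, bin_size = 10, library_total = 1)
  expect_true(all(unlist(tr0$values) == 0))
  expect_error(coverage_track(a[0, ], lens, bin_size = 10), "library_total")
})

test_that("uniform reads give Poisson-consistent bin values", {
  set.seed(5)
  n <- 20000; L <- 100000L; rl <- 50L
  a <- mk_genome_asn(sample.int(L - rl, n, replace = TRUE), len = rl)
  tr <- coverage_track(a, c(chr1 = L), bin_size = 100)
  v <- tr$values$chr1
  depth <- n * rl / L                       # expected per-base depth
  expect_lt(abs(mean(v) - depth * 1e6 / n), 0.02 * depth * 1e6 / n)
  # per-bin counts ~ Poisson(depth * bin / rl reads): >= 99% inside 3 sigma
  lam <- n * (100 + rl) / L                 # reads overlapping a bin
  counts <- v * 100 * n / 1e6 / rl          # approx overlapping read count
  inside <- mean(abs(counts - lam) < 3 * sqrt(lam) + 1)
  expect_gte(inside, 0.95)
})

test_that("window enrichment is zero for identical tracks and guarded by psi", {
  lens <- c(chr1 = 30000L)
  a <- mk_genome_asn(seq(0L, 29000L, by = 100L), len = 50L)
  tr <- coverage_track(a, lens, bin_size = 10)
  we <- window_enrichment(tr, tr, window = 10000)
  expect_true(all(we$enrichment == 0))
  empty <- coverage_track(a[0, ], lens, bin_size = 10, library_total = 10)
  we0 <- window_enrichment(empty, empty, window = 10000, psi = 1)
  expect_true(all(we0$enrichment == 0))
  tr2 <- coverage_track(a, c(chrX = 30000L), bin_size = 10,
                        library_total = 10)
  expect_error(window_enrichment(tr, tr2), "chromosomes")
})

test_that("euchromatin calling covers degenerate cases and is tau-monotone", {
  wins <- tidyr::expand_grid(chrom = c("c1", "c2"),
                             start = seq(0L, 90000L, by = 10000L)) |>
    dplyr::mutate(end = start + 10000L)
  low <- dplyr::mutate(wins, enrichment = -1)
  eu <- call_euchromatin(low, tau = 1)
  expect_equal(nrow(eu), 2L)
  expect_equal(eu$start, c(0L, 0L))
  expect_equal(eu$end, c(100000L, 100000L))
  high <- dplyr::mutate(wins, enrichment = 5)
  expect_equal(nrow(call_euchromatin(high, tau = 1)), 0L)
  set.seed(9)
  rnd <- dplyr::mutate(wins, enrichment = rnorm(dplyr::n(), 0.5, 1))
  covered_bp <- function(tau) sum(with(call_euchromatin(rnd, tau),
                                       end - start))
  taus <- seq(-2, 3, by = 0.5)
  expect_true(all(diff(vapply(taus, covered_bp, 1)) >= 0))
})

test_that("insertion matrices orient rows 5'->3' and match brute force", {
  set.seed(7)
  lens <- c(chr1 = 40000L, chr2 = 30000L)
  tr <- coverage_track(mk_genome_asn(0L, len = 10L), lens, bin_size = 10,
                       library_total = 10)
  tr$values$chr1 <- rnorm(4000)^2
  tr$values$chr2 <- rnorm(3000)^2
  ins <- tibble::tibble(
    id = paste0("i", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    midpoint = c(500L, 20000L, 39800L, 1000L, 15000L, 29000L),
    strand = c("+", "-", "+", "-", "+", "-"),
    family = "roo")
  sm <- insertion_matrix(tr, ins, flank = 2000)
  expect_equal(dim(sm$matrix), c(6L, 400L))
  # brute force oracle: per-coordinate lookup, written independently
  lookup <- function(chrom, coord) {
    v <- tr$values[[chrom]]
    i <- coord %/% 10 + 1
    if (i < 1 || i > length(v)) NA_real_ else v[i]
  }
  for (r in c(1L, 2L, 4L, 6L)) {
    expected <- vapply(0:399, function(j) {
      coord <- if (ins$strand[r] == "+")
        ins$midpoint[r] - 2000 + 10 * j
      else
        ins$midpoint[r] + 2000 - 10 * (j + 1)
      lookup(ins$chrom[r], coord)
    }, 1)
    expect_equal(unname(sm$matrix[r, ]), expected)
  }
  # orientation involution: flipping all strands reverses every row
  flipped <- dplyr::mutate(ins, strand = ifelse(strand == "+", "-", "+"))
  sm_f <- insertion_matrix(tr, flipped, flank = 2000)
  for (r in 1:6)
    expect_equal(unname(sm_f$matrix[r, ]), rev(unname(sm$matrix[r, ])))
  # unknown chromosome rows are skipped with a warning
  expect_warning(
    sm_u <- insertion_matrix(tr, dplyr::mutate(ins, chrom = "nope")[1, ],
                             flank = 2000),
    "unknown")
  expect_equal(nrow(sm_u$matrix), 0L)
  expect_error(insertion_matrix(tr, ins, flank = 1234), "multiple")
})

test_that("metaprofiles reduce to the row for single-row matrices", {
  tr <- coverage_track(mk_genome_asn(0L, len = 10L), c(chr1 = 10000L),
                       bin_size = 10, library_total = 10)
  tr$values$chr1 <- seq_len(1000) / 10
  ins <- tibble::tibble(id = "i1", chrom = "chr1", midpoint = 5000L,
                        strand = "+", family = "roo")
  sm <- insertion_matrix(tr, ins, flank = 1000)
  mp <- metaprofile(sm)
  expect_equal(mp$mean, unname(sm$matrix[1, ]))
  expect_true(all(mp$n == 1))
  # constant matrix: mean c, sd 0
  sm$matrix[] <- 3.5
  sm$matrix <- rbind(sm$matrix, sm$matrix)
  mp2 <- metaprofile(sm)
  expect_true(all(mp2$mean == 3.5))
  expect_true(all(mp2$sd == 0))
  sm$matrix <- sm$matrix[0, , drop = FALSE]
  expect_error(metaprofile(sm), "empty")
})

test_that("asymmetry scores are 1 for symmetric and all-zero rows", {
  row_sym <- c(5, 3, 1, 1, 3, 5)
  expect_equal(asymmetry_score(row_sym)$ratio, 1)
  expect_equal(asymmetry_score(rep(0, 10))$ratio, 1)
  row_down <- c(0, 0, 0, 4, 4, 4)
  expect_gt(asymmetry_score(row_down)$ratio, 1)
})

test_that("region means equal genome-wide means on full coverage regions", {
  set.seed(11)
  lens <- c(chr1 = 20000L, chr2 = 10000L)
  mk_tr <- function(seed) {
    set.seed(seed)
    tr <- coverage_track(mk_genome_asn(0L, len = 10L), lens, bin_size = 10,
                         library_total = 10)
    tr$values$chr1 <- rnorm(2000)^2
    tr$values$chr2 <- rnorm(1000)^2
    tr
  }
  tracks <- list(a1 = mk_tr(1), a2 = mk_tr(2), b1 = mk_tr(3), b2 = mk_tr(4))
  all_regions <- tibble::tibble(chrom = c("chr1", "chr2"),
                                start = c(0L, 0L), end = c(20000L, 10000L))
  rs <- region_mean_signal(tracks, all_regions,
                           groups = c(a1 = "a", a2 = "a",
                                      b1 = "b", b2 = "b"))
  gw <- vapply(tracks, function(t)
    mean(c(t$values$chr1, t$values$chr2)), 1)
  expect_equal(rs$replicates$mean_rpm, unname(gw))
  expect_false(rs$test$degenerate)
  # degenerate identical groups
  tracks_id <- list(a1 = mk_tr(5), a2 = mk_tr(5), b1 = mk_tr(5),
                    b2 = mk_tr(5))
  rs_id <- region_mean_signal(tracks_id, all_regions,
                              groups = c(a1 = "a", a2 = "a",
                                         b1 = "b", b2 = "b"))
  expect_true(rs_id$test$degenerate)
  expect_equal(rs_id$test$p_value, 1)
})
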