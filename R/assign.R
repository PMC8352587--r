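#' Build an exact k-mer seed index over a set of sequences
#'
#' Indexes every k-mer of each sequence on both strands to support
#' seed-and-verify lookup of reads with a bounded mismatch count. This is a
#' deliberately simple surrogate for a spliced aligner, adequate for
#' synthetic reads that are exact (or near-exact) substrings of their source.
#'
#' @param sequences named character vector (TE consensus library or genome).
#' @param k seed length (>= 11; default 21).
#' @return an object of class `seq_index`.
#' @export
build_index <- function(sequences, k = 21L) {
  if (k < 11L) abort("k must be >= 11")
  if (length(sequences) == 0L) abort("sequences must be non-empty")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    abort("sequences must have unique names")
  k <- as.integer(k)

  # oriented sequences: forward (+) then reverse complement (-) of each
  oriented <- c(sequences, revcomp(sequences))
  o_name <- rep(names(sequences), 2L)
  o_strand <- rep(c("+", "-"), each = length(sequences))
  o_len <- nchar(oriented)

  tabs <- lapply(seq_along(oriented), function(i) {
    n <- o_len[i] - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(
      kmer = substring(oriented[[i]], 1:n, k:o_len[i]),
      oid = i,
      start0 = 0:(n - 1L))
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)

  structure(list(
    dt = dt, oriented = unname(oriented), o_name = o_name,
    o_strand = o_strand, o_len = unname(o_len), k = k,
    seq_names = names(sequences)
  ), class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat("<seq_index> ", length(x$seq_names), " sequences, k = ", x$k,
      ", ", nrow(x$dt), " seed positions (both strands)\n", sep = "")
  invisible(x)
}

# seed-and-verify candidate hits for a batch of reads against one index.
# Returns a data.table: rid, oid, start0 (in oriented coordinates), mm.
# Two seeds per read (offset 0 and k) so one substitution cannot hide a hit.
index_candidates <- function(index, seqs, max_mismatches) {
  k <- index$k
  rlen <- nchar(seqs)
  q1 <- data.table::data.table(kmer = substr(seqs, 1L, k),
                               rid = seq_along(seqs), off = 0L)
  use2 <- rlen >= 2L * k
  q2 <- data.table::data.table(
    kmer = substr(seqs[use2], k + 1L, 2L * k),
    rid = which(use2), off = k)
  qs <- data.table::rbindlist(list(q1[nchar(q1$kmer) == k], q2))
  hits <- index$dt[qs, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) {
    return(data.table::data.table(rid = integer(0), oid = integer(0),
                                  start0 = integer(0), mm = integer(0)))
  }
  hits[, start0 := start0 - off]
  hits <- unique(hits[, c("rid", "oid", "start0")])
  hits <- hits[hits$start0 >= 0L &
                 hits$start0 + rlen[hits$rid] <= index$o_len[hits$oid], ]
  if (nrow(hits) == 0L) return(cbind(hits, mm = integer(0)))
  ref <- substring(index$oriented[hits$oid], hits$start0 + 1L,
                   hits$start0 + rlen[hits$rid])
  qry <- seqs[hits$rid]
  mmv <- integer(nrow(hits))
  ne <- ref != qry
  if (max_mismatches > 0L && any(ne))
    mmv[ne] <- count_mismatches(qry[ne], ref[ne])
  else
    mmv[ne] <- max_mismatches + 1L
  hits[, mm := mmv]
  hits[hits$mm <= max_mismatches, ]
}

#' Assign reads to TE families or unique genome loci (two-tier policy)
#'
#' Tier 1: a read with at least one TE-consensus hit at its best mismatch
#' count is assigned to a TE family; ties among equal-best families are
#' broken by a seeded uniform draw that advances per read in input order
#' (random allocation of multimappers). Tier 2: otherwise, a read with
#' exactly one best genome locus is assigned uniquely to the genome. Tier 3:
#' everything else (including genome multimappers) is `UNMAPPED`.
#'
#' @param reads tibble with `read_id` and `seq` (optionally `mate`).
#' @param te_index,genome_index [build_index()] objects built with the same
#'   `k`. Either may be `NULL` to skip that tier.
#' @param max_mismatches maximum substitutions allowed for a hit (default 2).
#' @param seed integer seed for multimapper allocation; changing it changes
#'   only tied-family choices, never categories.
#' @return tibble with one row per read: `read_id`, `mate`, `category`
#'   (`TE`/`GENOME`/`UNMAPPED`), `target` (family or chromosome; `NA` if
#'   unmapped), `pos` (0-based leftmost, forward-strand coordinates),
#'   `strand`, `len`, `unique`, `n_candidates`, `mismatches`.
#' @export
assign_reads <- function(reads, te_index = NULL, genome_index = NULL,
                         max_mismatches = 2L, seed = 1L) {
  if (!is.null(te_index) && !is.null(genome_index) &&
      te_index$k != genome_index$k)
    abort("te_index and genome_index must share the same k")
  n <- nrow(reads)
  seqs <- reads$seq
  rlen <- nchar(seqs)
  out <- tibble(
    read_id = reads$read_id,
    mate = if ("mate" %in% names(reads)) reads$mate else NA_integer_,
    category = rep("UNMAPPED", n),
    target = NA_character_, pos = NA_integer_, strand = NA_character_,
    len = rlen, unique = FALSE, n_candidates = 0L, mismatches = NA_integer_)
  if (n == 0L) return(out)

  # one uniform per read, drawn up front: the allocation stream advances per
  # read in input order regardless of how many reads are actually tied
  set.seed(seed)
  u <- runif(n)

  # keep rows carrying the per-read minimum mismatch count (vectorised)
  best_hits <- function(cand) {
    cand[, mm := as.integer(mm)]
    cand[, `:=`(mmin = min(mm)), by = rid]
    best <- cand[cand$mm == cand$mmin]
    best[, mmin := NULL]
    best
  }

  te_done <- rep(FALSE, n)
  if (!is.null(te_index)) {
    cand <- index_candidates(te_index, seqs, max_mismatches)
    if (nrow(cand) > 0L) {
      data.table::set(cand, j = "family", value = te_index$o_name[cand$oid])
      best <- best_hits(cand)
      data.table::setorder(best, rid, family, oid, start0)
      fu <- unique(best[, c("rid", "family")])
      first <- which(!duplicated(fu$rid))
      n_fam_per <- diff(c(first, nrow(fu) + 1L))
      rids <- fu$rid[first]
      choice <- pmin(floor(u[rids] * n_fam_per), n_fam_per - 1L)
      chosen <- fu[first + choice]
      data.table::set(chosen, j = "n_fam", value = n_fam_per)
      pick <- best[chosen, on = c("rid", "family"), mult = "first"]
      idx <- pick$rid
      te_done[idx] <- TRUE
      out$category[idx] <- "TE"
      out$target[idx] <- pick$family
      out$strand[idx] <- te_index$o_strand[pick$oid]
      out$pos[idx] <- ifelse(
        te_index$o_strand[pick$oid] == "+", pick$start0,
        te_index$o_len[pick$oid] - pick$start0 - rlen[idx])
      out$unique[idx] <- pick$n_fam == 1L
      out$n_candidates[idx] <- pick$n_fam
      out$mismatches[idx] <- pick$mm
    }
  }

  if (!is.null(genome_index) && any(!te_done)) {
    rest <- which(!te_done)
    cand <- index_candidates(genome_index, seqs[rest], max_mismatches)
    if (nrow(cand) > 0L) {
      best <- best_hits(cand)
      data.table::setorder(best, rid, oid, start0)
      # a locus is (oriented sequence, start): rows are already distinct loci
      first <- which(!duplicated(best$rid))
      n_loci <- diff(c(first, nrow(best) + 1L))
      su <- best[first]
      idx <- rest[su$rid]
      uniq <- n_loci == 1L
      out$n_candidates[idx] <- n_loci
      gi <- idx[uniq]
      su <- su[uniq]
      out$category[gi] <- "GENOME"
      out$target[gi] <- genome_index$o_name[su$oid]
      out$strand[gi] <- genome_index$o_strand[su$oid]
      out$pos[gi] <- ifelse(
        genome_index$o_strand[su$oid] == "+", su$start0,
        genome_index$o_len[su$oid] - su$start0 - rlen[gi])
      out$unique[gi] <- TRUE
      out$mismatches[gi] <- su$mm
    }
  }
  out
}

#' Count assigned reads per feature
#'
#' TE-category reads are counted per family; GENOME-category reads per
#' chromosome (or per custom feature via `genome_feature`). The library
#' total -- the rpm denominator -- is the number of TE plus GENOME assigned
#' reads; UNMAPPED reads are excluded.
#'
#' @param assignments an [assign_reads()] tibble.
#' @param features optional character vector fixing the feature universe
#'   (zero-filled); defaults to the observed targets.
#' @return tibble `feature`, `category`, `count` with attribute
#'   `library_total`.
#' @export
count_features <- function(assignments, features = NULL) {
  mapped <- dplyr::filter(assignments, .data$category != "UNMAPPED")
  counts <- mapped |>
    dplyr::count(.data$category, .data$target, name = "count") |>
    dplyr::rename(feature = "target") |>
    dplyr::select("feature", "category", "count")
  if (!is.null(features)) {
    counts <- tibble(feature = features) |>
      dplyr::left_join(counts, by = "feature") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  }
  attr(counts, "library_total") <- nrow(mapped)
  counts
}

#' rpm-normalize a count table
#'
#' `rpm = count * 1e6 / library_total`, where the library total is the sum of
#' all TE-consensus plus genome-mapped reads of the library.
#'
#' @param counts a [count_features()] tibble (or any tibble with a `count`
#'   column).
#' @param library_total defaults to the `library_total` attribute of `counts`.
#' @return the input tibble with an `rpm` column.
#' @export
rpm_normalize <- function(counts, library_total = NULL) {
  library_total <- library_total %||% attr(counts, "library_total")
  if (is.null(library_total) || library_total <= 0)
    abort("library_total must be > 0 for rpm normalization")
  out <- dplyr::mutate(counts, rpm = .data$count * 1e6 / library_total)
  attr(out, "library_total") <- library_total
  out
}

#' Per-file scaling factor onto the whole-library rpm scale
#'
#' The multiplier that converts a per-file CPM track onto the rpm scale of
#' the full library: the file's mapped reads divided by the library's mapped
#' total (TE + genome).
#'
#' @param file_reads mapped reads contained in the file.
#' @param library_total all TE + genome mapped reads of the library.
#' @return a numeric scaling factor.
#' @export
scaling_factor <- function(file_reads, library_total) {
  if (library_total <= 0) abort("library_total must be > 0")
  file_reads / library_total
}

#' TE transcriptome fractions across a developmental time course
#'
#' @param rpm_tables named list (timepoint -> [rpm_normalize()] table) or a
#'   long tibble with columns `timepoint`, `feature`, `category`, `rpm`.
#' @param top_n restrict the per-family table to the top families by their
#'   peak percentage (default all).
#' @return list with `total` (tibble `timepoint`, `te_pct`) and `by_family`
#'   (tibble `timepoint`, `family`, `pct`, `rank`); percentages are of the
#'   whole transcriptome (family rpm / 1e4).
#' @export
te_fraction_timecourse <- function(rpm_tables, top_n = Inf) {
  long <- if (is.data.frame(rpm_tables)) {
    tibble::as_tibble(rpm_tables)
  } else {
    dplyr::bind_rows(rpm_tables, .id = "timepoint")
  }
  te <- dplyr::filter(long, .data$category == "TE")
  tps <- unique(long$timepoint)
  total <- tibble(timepoint = tps) |>
    dplyr::left_join(
      te |> dplyr::group_by(.data$timepoint) |>
        dplyr::summarise(te_pct = sum(.data$rpm) / 1e4, .groups = "drop"),
      by = "timepoint") |>
    dplyr::mutate(te_pct = dplyr::coalesce(.data$te_pct, 0))
  by_family <- te |>
    dplyr::group_by(.data$timepoint, family = .data$feature) |>
    dplyr::summarise(pct = sum(.data$rpm) / 1e4, .groups = "drop") |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$pct))) |>
    dplyr::ungroup()
  if (is.finite(top_n) && nrow(by_family) > 0) {
    keep <- by_family |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(peak = max(.data$pct), .groups = "drop") |>
      dplyr::slice_max(.data$peak, n = top_n, with_ties = FALSE)
    by_family <- dplyr::semi_join(by_family, keep, by = "family")
  }
  list(total = total, by_family = by_family)
}
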