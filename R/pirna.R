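#' Clip 3' adapters and trim random linker nucleotides from small RNA reads
#'
#' The adapter is located as the longest suffix of the read matching a prefix
#' of the adapter: the first 5 nt of the adapter must match exactly (seed),
#' and the full suffix may carry at most one mismatch per 10 nt. Reads
#' shorter than `min_len_postclip` after clipping are discarded; surviving
#' reads then lose `trim_each_side` nt from each end (the random linker
#' nucleotides added during library preparation). Reads with no detectable
#' adapter are retained unclipped unless `discard_unclipped`.
#'
#' @param reads tibble with `read_id`, `seq`.
#' @param adapter 3' adapter sequence (default the TruSeq small RNA adapter).
#' @param min_len_postclip minimum read length after clipping (default 15).
#' @param trim_each_side nucleotides trimmed from each end after clipping
#'   (default 4).
#' @param discard_unclipped drop reads without a detectable adapter.
#' @return tibble `read_id`, `seq` (processed insert), `len`, `clipped`.
#' @export
clip_and_trim <- function(reads, adapter = "AGATCGGAAGAGCACACGTCT",
                          min_len_postclip = 15L, trim_each_side = 4L,
                          discard_unclipped = FALSE) {
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  seed <- substr(adapter, 1L, 5L)
  find_adapter <- function(s) {
    # leftmost seed occurrence whose full adapter-prefix suffix verifies
    occ <- gregexpr(seed, s, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) return(NA_integer_)
    n <- nchar(s)
    for (i in occ) {
      len <- min(n - i + 1L, nchar(adapter))
      mm <- count_mismatches(substr(s, i, i + len - 1L),
                             substr(adapter, 1L, len))
      if (mm <= floor(len / 10)) return(i)
    }
    NA_integer_
  }
  at <- vapply(reads$seq, find_adapter, 1L, USE.NAMES = FALSE)
  clipped <- !is.na(at)
  s <- reads$seq
  s[clipped] <- substr(s[clipped], 1L, at[clipped] - 1L)
  keep <- nchar(s) >= min_len_postclip & (clipped | !discard_unclipped)
  s <- s[keep]
  s <- substr(s, trim_each_side + 1L, nchar(s) - trim_each_side)
  tibble(read_id = reads$read_id[keep], seq = s, len = nchar(s),
         clipped = clipped[keep])
}

#' Inclusive length filter for small RNA reads
#'
#' @param reads tibble with `seq` (and optionally `len`).
#' @param lo,hi inclusive bounds in nt (defaults 19 and 31).
#' @return the filtered tibble (with `len` set).
#' @export
size_filter <- function(reads, lo = 19L, hi = 31L) {
  reads$len <- nchar(reads$seq)
  reads[reads$len >= lo & reads$len <= hi, , drop = FALSE]
}

#' Assign small RNAs to TE families with sense/antisense orientation
#'
#' A read matching a consensus on the `+` strand is sense; a read that is the
#' reverse complement of consensus sequence is antisense. Ties among
#' equal-best families are broken by the seeded multimapper rule of
#' [assign_reads()].
#'
#' @param reads tibble with `read_id`, `seq`.
#' @param te_index a [build_index()] over the consensus library. Small RNAs
#'   are shorter than typical seeds, so use a k of at most the shortest
#'   read length (e.g. `k = 15`).
#' @param max_mismatches allowed substitutions (default 0).
#' @param seed multimapper allocation seed.
#' @return tibble `read_id`, `seq`, `len`, `family`, `orientation`
#'   (`sense`/`antisense`/`NA` for unassigned).
#' @export
orient_and_assign <- function(reads, te_index, max_mismatches = 0L,
                              seed = 1L) {
  asn <- assign_reads(reads, te_index = te_index, genome_index = NULL,
                      max_mismatches = max_mismatches, seed = seed)
  tibble(
    read_id = reads$read_id,
    seq = reads$seq,
    len = nchar(reads$seq),
    family = ifelse(asn$category == "TE", asn$target, NA_character_),
    orientation = dplyr::case_when(
      asn$category != "TE" ~ NA_character_,
      asn$strand == "+" ~ "sense",
      TRUE ~ "antisense"))
}

#' Read-length profile split by orientation
#'
#' @param assigned an [orient_and_assign()] tibble.
#' @param lo,hi profile support in nt (defaults 19 and 31).
#' @param by_family also split counts per family.
#' @return tibble `length`, `orientation`, (`family`,) `count`, zero-filled
#'   over the full support.
#' @export
size_profile <- function(assigned, lo = 19L, hi = 31L, by_family = FALSE) {
  a <- dplyr::filter(assigned, !is.na(.data$orientation))
  keys <- if (by_family) c("len", "orientation", "family")
    else c("len", "orientation")
  counted <- a |> dplyr::count(dplyr::across(dplyr::all_of(keys)),
                               name = "count")
  grid <- tidyr::expand_grid(
    length = lo:hi, orientation = c("sense", "antisense"))
  if (by_family)
    grid <- tidyr::expand_grid(grid,
                               family = sort(unique(a$family)))
  grid |>
    dplyr::left_join(counted,
                     by = c(stats::setNames("len", "length"),
                            "orientation",
                            if (by_family) "family")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Per-family share of all TE-mapping antisense piRNAs
#'
#' `pct(F) = 100 * antisense(F) / sum_G antisense(G)`; percentages over ALL
#' families sum to 100, and the returned table is restricted to the `top_n`
#' most abundant families by antisense count.
#'
#' @param assigned an [orient_and_assign()] tibble.
#' @param top_n families to keep (default 30).
#' @return tibble `family`, `antisense_count`, `pct`, ranked by abundance.
#' @export
antisense_fraction_table <- function(assigned, top_n = 30L) {
  anti <- dplyr::filter(assigned, .data$orientation == "antisense")
  if (nrow(anti) == 0L) abort("no antisense TE-mapping reads")
  tab <- anti |>
    dplyr::count(.data$family, name = "antisense_count") |>
    dplyr::mutate(pct = 100 * .data$antisense_count /
                    sum(.data$antisense_count)) |>
    dplyr::arrange(dplyr::desc(.data$antisense_count))
  head(tab, top_n)
}
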