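#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads as FASTQ (Phred-33, constant quality)
#'
#' @param reads tibble with `read_id`, `seq` (and optionally `mate`, appended
#'   to the id as `/1`, `/2`).
#' @param path output file.
#' @param quality_char quality character for every base (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- reads$read_id
  if ("mate" %in% names(reads) && !all(is.na(reads$mate)))
    ids <- paste0(ids, "/", reads$mate)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file.
#' @return tibble `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = unname(as.character(x)))
}

#' Write insertions as BED6 (+ support and midpoint columns)
#'
#' Columns: chrom, start, end (0-based half-open junction interval), family,
#' score 0, strand, support_left, support_right, midpoint.
#'
#' @param insertions a [cluster_and_call()] tibble or the truth table of a
#'   [build_genome()] (junction point used for both start and end).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_insertions_bed <- function(insertions, path) {
  x <- tibble::as_tibble(insertions)
  if (!"start" %in% names(x)) {
    x$start <- x$pos
    x$end <- x$pos
  }
  if (!"midpoint" %in% names(x))
    x$midpoint <- as.integer(floor((x$start + x$end) / 2))
  if (!"support_left" %in% names(x)) x$support_left <- 0L
  if (!"support_right" %in% names(x)) x$support_right <- 0L
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = x$family, score = 0L, strand = x$strand,
                support_left = x$support_left,
                support_right = x$support_right, midpoint = x$midpoint)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6(+) insertion file
#'
#' @param path BED file written by [write_insertions_bed()].
#' @return tibble `chrom`, `start`, `end`, `family`, `strand` (+ support and
#'   midpoint columns when present).
#' @export
read_insertions_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(x)[1:6] <- c("chrom", "start", "end", "family", "score", "strand")
  if (ncol(x) >= 9L)
    names(x)[7:9] <- c("support_left", "support_right", "midpoint")
  dplyr::select(x, -"score")
}

#' Write a coverage track as 4-column bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    L <- track$chrom_lengths[[ch]]
    starts <- (seq_along(v) - 1L) * track$bin_size
    tibble(chrom = ch, start = starts,
           end = pmin(starts + track$bin_size, L), value = v)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, col_names = FALSE)
  invisible(path)
}

#' Read a minimal SAM subset into an assignment tibble
#'
#' Parses QNAME, FLAG, RNAME, POS and MAPQ of an uncompressed SAM file so
#' pre-aligned data can bypass the built-in aligner surrogate. Uniqueness
#' follows the MAPQ-255 convention: records with `MAPQ == 255` (or
#' `MAPQ >= unique_mapq`) are treated as unique. Coordinates are converted
#' from SAM's 1-based to the package's 0-based convention. Records aligned to
#' sequences named in `te_names` become TE-category assignments; unmapped
#' flags (0x4) become `UNMAPPED`.
#'
#' @param path SAM file (headers ignored).
#' @param te_names character vector of TE consensus sequence names.
#' @param unique_mapq MAPQ at or above which an alignment counts as unique
#'   (default 255).
#' @return an [assign_reads()]-shaped tibble.
#' @export
read_sam_subset <- function(path, te_names = character(0),
                            unique_mapq = 255L) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(assign_reads(tibble(read_id = character(0), seq = character(0))))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2L))
  seq <- get(10L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  is_te <- get(3L) %in% te_names
  mapq <- as.integer(get(5L))
  mate <- dplyr::case_when(
    bitwAnd(flag, 64L) > 0L ~ 1L,
    bitwAnd(flag, 128L) > 0L ~ 2L,
    TRUE ~ NA_integer_)
  uniq <- !unmapped & mapq >= unique_mapq
  # genome multimappers are discarded under the two-tier policy
  category <- dplyr::case_when(
    unmapped ~ "UNMAPPED",
    is_te ~ "TE",
    uniq ~ "GENOME",
    TRUE ~ "UNMAPPED")
  tibble(
    read_id = get(1L),
    mate = mate,
    category = category,
    target = ifelse(category == "UNMAPPED", NA_character_, get(3L)),
    pos = ifelse(category == "UNMAPPED", NA_integer_,
                 as.integer(get(4L)) - 1L),
    strand = ifelse(category == "UNMAPPED", NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    len = ifelse(seq == "*", NA_integer_, nchar(seq)),
    unique = uniq,
    n_candidates = ifelse(category == "UNMAPPED", 0L, 1L),
    mismatches = NA_integer_)
}

#' Write a simulated genome bundle to disk
#'
#' Emits `reference.fa`, `sample.fa`, `te_consensus.fa` (60-column FASTA),
#' `truth_insertions.bed` (junction points, BED6+) and `regions.bed`
#' (chromosome class intervals, BED4) into a directory.
#'
#' @param genome a [build_genome()] result.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_genome_bundle <- function(genome, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome$reference, file.path(outdir, "reference.fa"))
  write_fasta(genome$sample, file.path(outdir, "sample.fa"))
  write_fasta(genome$te_seqs, file.path(outdir, "te_consensus.fa"))
  write_insertions_bed(genome$insertions,
                       file.path(outdir, "truth_insertions.bed"))
  readr::write_tsv(genome$regions[, c("chrom", "start", "end", "class")],
                   file.path(outdir, "regions.bed"), col_names = FALSE)
  invisible(outdir)
}
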