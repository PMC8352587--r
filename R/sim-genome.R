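#' Build a reference/sample genome pair with planted TE insertions
#'
#' Generates a random background genome (the "reference"), per-family TE
#' consensus sequences, and a "sample" genome identical to the reference
#' except that full-length consensus copies are spliced in at planted
#' euchromatic positions (no target-site duplication). The planted insertions
#' are strain-specific: present in the sample, absent from the reference, so
#' they are discoverable only from junction-spanning read pairs.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_genome`: a list with
#'   * `reference`, `sample`: named character vectors of chromosome sequences,
#'   * `te_seqs`: named character vector of family consensus sequences,
#'   * `regions`: tibble of chromosome class intervals
#'     (`chrom`, `start`, `end`, `class`; 0-based half-open),
#'   * `insertions`: truth tibble (`id`, `chrom`, `pos` junction in reference
#'     coordinates, `family`, `strand`, `sample_start`, `sample_end`,
#'     `source = "planted"`),
#'   * `config`: the input `cfg`.
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$master_seed, 0L))

  reference <- setNames(
    vapply(seq_len(nrow(cfg$chrom_specs)), function(i)
      random_dna(cfg$chrom_specs$length[i], cfg$genome_gc), ""),
    cfg$chrom_specs$name)

  te_seqs <- setNames(
    vapply(seq_len(nrow(cfg$te_families)), function(i)
      random_dna(cfg$te_families$length[i], cfg$te_families$gc[i]), ""),
    cfg$te_families$name)

  regions <- tibble(
    chrom = cfg$chrom_specs$name,
    start = 0L,
    end   = cfg$chrom_specs$length,
    class = cfg$chrom_specs$class
  )

  insertions <- plant_insertions(cfg)

  sample_seqs <- reference
  if (nrow(insertions) > 0) {
    ins_by_chrom <- split(insertions, insertions$chrom)
    for (chrom in names(ins_by_chrom)) {
      ins <- dplyr::arrange(ins_by_chrom[[chrom]], .data$pos)
      seq <- reference[[chrom]]
      pieces <- character(2L * nrow(ins) + 1L)
      prev <- 0L
      for (j in seq_len(nrow(ins))) {
        te <- te_seqs[[ins$family[j]]]
        if (ins$strand[j] == "-") te <- revcomp(te)
        pieces[2L * j - 1L] <- substr(seq, prev + 1L, ins$pos[j])
        pieces[2L * j] <- te
        prev <- ins$pos[j]
      }
      pieces[2L * nrow(ins) + 1L] <- substr(seq, prev + 1L, nchar(seq))
      sample_seqs[[chrom]] <- paste(pieces, collapse = "")
    }
    # junction position in sample coordinates (element occupies
    # [sample_start, sample_end))
    te_len <- setNames(nchar(te_seqs), names(te_seqs))
    insertions <- insertions |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$pos, .by_group = TRUE) |>
      dplyr::mutate(
        sample_start = .data$pos +
          cumsum(dplyr::lag(te_len[.data$family], default = 0L)),
        sample_end = .data$sample_start + te_len[.data$family]
      ) |>
      dplyr::ungroup()
  } else {
    insertions$sample_start <- integer(0)
    insertions$sample_end <- integer(0)
  }

  structure(list(
    reference = reference,
    sample = sample_seqs,
    te_seqs = te_seqs,
    regions = regions,
    insertions = insertions,
    config = cfg
  ), class = "sim_genome")
}

# uniform placement over euchromatic space with a minimum junction spacing
plant_insertions <- function(cfg) {
  eu <- dplyr::filter(cfg$chrom_specs, .data$class == "euchromatin")
  n_total <- sum(cfg$n_insertions)
  empty <- tibble(
    id = character(0), chrom = character(0), pos = integer(0),
    family = character(0), strand = character(0), source = character(0))
  if (n_total == 0L) return(empty)
  margin <- 1000L
  usable <- sum(pmax(eu$length - 2L * margin, 0L))
  if (nrow(eu) == 0L || usable < n_total * cfg$min_spacing) {
    abort(paste0(
      "cannot place ", n_total, " insertions with spacing ", cfg$min_spacing,
      " bp in ", usable, " bp of euchromatin (chromosomes: ",
      paste(eu$name, collapse = ", "), ")"))
  }
  fams <- rep(names(cfg$n_insertions), times = cfg$n_insertions)
  fams <- sample(fams)  # interleave families along the genome
  placed <- vector("list", n_total)
  by_chrom <- setNames(vector("list", nrow(eu)), eu$name)
  for (i in seq_len(n_total)) {
    ok <- FALSE
    for (try in 1:2000) {
      ci <- sample.int(nrow(eu), 1L, prob = eu$length)
      chrom <- eu$name[ci]
      pos <- margin + sample.int(eu$length[ci] - 2L * margin, 1L)
      if (!length(by_chrom[[chrom]]) ||
          min(abs(by_chrom[[chrom]] - pos)) >= cfg$min_spacing) {
        ok <- TRUE
        break
      }
    }
    if (!ok) abort(paste0("failed to place insertion ", i,
                          " with spacing ", cfg$min_spacing, " bp"))
    by_chrom[[chrom]] <- c(by_chrom[[chrom]], pos)
    placed[[i]] <- tibble(chrom = chrom, pos = pos, family = fams[i])
  }
  dplyr::bind_rows(placed) |>
    dplyr::mutate(
      strand = ifelse(runif(dplyr::n()) < cfg$strand_prob, "+", "-"),
      id = paste0("ins", sprintf("%03d", dplyr::row_number())),
      source = "planted"
    ) |>
    dplyr::select("id", "chrom", "pos", "family", "strand", "source") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>\n")
  cat("  reference: ", length(x$reference), " chromosomes, ",
      sum(nchar(x$reference)), " bp\n", sep = "")
  cat("  sample:    ", sum(nchar(x$sample)), " bp (",
      nrow(x$insertions), " planted insertions)\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a simulated genome
#'
#' @param genome a `sim_genome`.
#' @param which `"reference"` or `"sample"`.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome, which = c("reference", "sample")) {
  which <- match.arg(which)
  setNames(nchar(genome[[which]]), names(genome[[which]]))
}
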