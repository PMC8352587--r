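#' Simulate an RNA-seq library for one developmental timepoint
#'
#' Each read is drawn from a TE family with its configured fraction of the
#' transcriptome at that timepoint (uniform position on the consensus, sense
#' strand of the transcript), or otherwise from background "genic" sequence,
#' taken uniformly from the euchromatic portion of the sample genome with a
#' random strand. Substitution errors are applied at `cfg$error_rate`.
#'
#' @param genome a [build_genome()] result.
#' @param cfg the [sim_config()].
#' @param timepoint a label present in `cfg$expression_profile`.
#' @param n_reads number of reads (> 0).
#' @param seed integer seed for this library.
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   `read_id`, `origin` in `TE`/`genome`, `target`, `position`, `strand`,
#'   `timepoint`); exactly one truth row per read.
#' @export
simulate_rnaseq <- function(genome, cfg, timepoint, n_reads, seed = 1L) {
  if (n_reads <= 0) abort("n_reads must be > 0")
  ep <- dplyr::filter(cfg$expression_profile, .data$timepoint == !!timepoint)
  if (nrow(ep) == 0L)
    abort(paste0("timepoint '", timepoint, "' not in expression profile"))
  set.seed(seed)
  rl <- cfg$rna_read_length

  fams <- ep$family
  probs <- c(ep$fraction, 1 - sum(ep$fraction))
  origin <- sample(c(fams, ".genome"), n_reads, replace = TRUE, prob = probs)

  seqs <- character(n_reads)
  target <- character(n_reads)
  position <- integer(n_reads)
  strand <- character(n_reads)

  is_te <- origin != ".genome"
  for (fam in unique(origin[is_te])) {
    idx <- which(origin == fam)
    cons <- genome$te_seqs[[fam]]
    starts <- sample.int(nchar(cons) - rl + 1L, length(idx), replace = TRUE) - 1L
    seqs[idx] <- substring(cons, starts + 1L, starts + rl)
    target[idx] <- fam
    position[idx] <- starts
    strand[idx] <- "+"
  }
  n_bg <- sum(!is_te)
  if (n_bg > 0) {
    # background "genic" space is the euchromatic reference sequence, i.e.
    # everything that is not a TE copy; positions are reference coordinates
    eu <- dplyr::filter(genome$regions, .data$class == "euchromatin")
    lens <- setNames(nchar(genome$reference[eu$chrom]), eu$chrom)
    chroms <- sample(names(lens), n_bg, replace = TRUE, prob = lens)
    starts <- as.integer(floor(runif(n_bg) * (lens[chroms] - rl + 1)))
    st <- sample(c("+", "-"), n_bg, replace = TRUE)
    s <- unname(substring(genome$reference[chroms], starts + 1L, starts + rl))
    s[st == "-"] <- revcomp(s[st == "-"])
    idx <- which(!is_te)
    seqs[idx] <- s
    target[idx] <- chroms
    position[idx] <- starts
    strand[idx] <- st
  }

  seqs <- apply_errors(seqs, cfg$error_rate)
  ids <- sprintf("rna_%s_%07d", gsub("[^A-Za-z0-9]", "", timepoint),
                 seq_len(n_reads))
  list(
    reads = tibble(read_id = ids, seq = seqs),
    truth = tibble(
      read_id = ids,
      origin = ifelse(is_te, "TE", "genome"),
      target = target, position = position, strand = strand,
      timepoint = timepoint)
  )
}

# additive kernel weight grid over the sample genome; resolution `gres` bp.
# Excess over background is lag * scale_family * (E0 - 1) * exp(-d/lambda_side),
# summed over insertions; d = 0 inside the element; downstream decay length is
# lambda * skew in the element's 5'->3' direction.
chip_weight_grid <- function(genome, cfg, lagv, kernel_scale_by_family = NULL,
                             gres = 25L) {
  kern <- cfg$chip_kernel
  lens <- chrom_lengths(genome, "sample")
  classes <- setNames(genome$regions$class, genome$regions$chrom)
  grids <- lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / gres)
    w <- rep(1, n)
    if (classes[[ch]] == "heterochromatin_block") w[] <- kern$het_fold
    if (classes[[ch]] == "chr4_like") w[] <- kern$chr4_fold
    w
  })
  names(grids) <- names(lens)
  ins <- genome$insertions
  if (nrow(ins) > 0 && lagv > 0) {
    reach <- ceiling(6 * kern$lambda * max(1, kern$skew))
    for (j in seq_len(nrow(ins))) {
      ch <- ins$chrom[j]
      scale_f <- 1
      if (!is.null(kernel_scale_by_family) &&
          ins$family[j] %in% names(kernel_scale_by_family))
        scale_f <- kernel_scale_by_family[[ins$family[j]]]
      amp <- lagv * scale_f * (kern$E0 - 1)
      if (amp <= 0) next
      s <- ins$sample_start[j]; e <- ins$sample_end[j]
      lam_left <- if (ins$strand[j] == "+") kern$lambda else kern$lambda * kern$skew
      lam_right <- if (ins$strand[j] == "+") kern$lambda * kern$skew else kern$lambda
      i_lo <- max(1L, floor((s - reach) / gres) + 1L)
      i_hi <- min(length(grids[[ch]]), ceiling((e + reach) / gres))
      centers <- (seq(i_lo, i_hi) - 0.5) * gres
      d_left <- pmax(0, s - centers)
      d_right <- pmax(0, centers - e)
      d <- pmax(d_left, d_right)
      lam <- ifelse(centers < s, lam_left, ifelse(centers >= e, lam_right, Inf))
      excess <- ifelse(d == 0, amp, amp * exp(-d / lam))
      grids[[ch]][i_lo:i_hi] <- grids[[ch]][i_lo:i_hi] + excess
    }
  }
  grids
}

#' Simulate a ChIP-seq IP/input library pair
#'
#' Input reads are sampled uniformly along the sample genome. IP reads are
#' sampled with relative density `1 + lag(t) * (E0 - 1) * exp(-d / lambda_side)`
#' around each planted insertion, where the decay length is `lambda`
#' upstream and `lambda * skew` downstream of the element in its 5'->3'
#' direction (excess terms add across insertions). The heterochromatin block
#' and the chr4-like chromosome receive constant configured enrichments.
#'
#' @inheritParams simulate_rnaseq
#' @param n_reads_ip,n_reads_input read counts for the IP and input libraries.
#' @param kernel_scale_by_family optional named multiplier in `[0, 1]` on the
#'   kernel amplitude per TE family (e.g. to switch off the chromatin
#'   response at one family's insertions under a depletion condition).
#' @return list with `ip`, `input` (tibbles `read_id`, `seq`), `truth`
#'   (per-read origin tibble), and `kernel` (the realized kernel parameters).
#' @export
simulate_chip <- function(genome, cfg, timepoint, n_reads_ip, n_reads_input,
                          seed = 1L, kernel_scale_by_family = NULL) {
  kern <- cfg$chip_kernel
  if (!timepoint %in% names(kern$lag))
    abort(paste0("timepoint '", timepoint, "' missing from the kernel lag map"))
  set.seed(seed)
  lagv <- kern$lag[[timepoint]]
  rl <- cfg$chip_read_length
  lens <- chrom_lengths(genome, "sample")
  gres <- 25L

  grids <- chip_weight_grid(genome, cfg, lagv, kernel_scale_by_family, gres)

  sample_positions <- function(n, weighted) {
    if (weighted) {
      w <- unlist(grids, use.names = FALSE)
      nb <- vapply(grids, length, 1L)
      bin <- sample.int(length(w), n, replace = TRUE, prob = w)
      chrom_idx <- findInterval(bin, cumsum(nb), left.open = TRUE) + 1L
      chrom <- names(grids)[chrom_idx]
      local_bin <- bin - c(0L, cumsum(nb))[chrom_idx]
      pos <- (local_bin - 1L) * gres +
        sample.int(gres, n, replace = TRUE) - 1L
    } else {
      chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
      pos <- floor(runif(n) * (lens[chrom] - rl))
    }
    pos <- pmin(pmax(pos, 0L), lens[chrom] - rl)
    tibble(chrom = chrom, position = as.integer(pos),
           strand = sample(c("+", "-"), n, replace = TRUE))
  }
  extract <- function(df) {
    s <- unname(substring(genome$sample[df$chrom], df$position + 1L, df$position + rl))
    s[df$strand == "-"] <- revcomp(s[df$strand == "-"])
    apply_errors(s, cfg$error_rate)
  }

  tp_tag <- gsub("[^A-Za-z0-9]", "", timepoint)
  ip_pos <- sample_positions(n_reads_ip, weighted = TRUE)
  ip_ids <- sprintf("chip_%s_ip_%07d", tp_tag, seq_len(n_reads_ip))
  input_pos <- sample_positions(n_reads_input, weighted = FALSE)
  input_ids <- sprintf("chip_%s_in_%07d", tp_tag, seq_len(n_reads_input))

  truth <- dplyr::bind_rows(
    dplyr::mutate(ip_pos, read_id = ip_ids, library = "ip"),
    dplyr::mutate(input_pos, read_id = input_ids, library = "input")
  ) |>
    dplyr::mutate(origin = "genome", timepoint = timepoint) |>
    dplyr::select("read_id", "library", "origin", chrom = "chrom",
                  "position", "strand", "timepoint")

  list(
    ip = tibble(read_id = ip_ids, seq = extract(ip_pos)),
    input = tibble(read_id = input_ids, seq = extract(input_pos)),
    truth = truth,
    kernel = list(E0 = kern$E0, lambda = kern$lambda, skew = kern$skew,
                  lag = lagv, het_fold = kern$het_fold,
                  chr4_fold = kern$chr4_fold,
                  kernel_scale_by_family = kernel_scale_by_family)
  )
}

#' Simulate paired-end WGS of the insertion-bearing sample genome
#'
#' Fragment count is Poisson with mean `coverage * genome_length /
#' (2 * read_length)`; fragment lengths are Gaussian. Mates are read-length
#' prefixes of the two fragment ends in FR orientation (mate 2
#' reverse-complemented). Fragments overlapping a planted junction are tagged
#' `junction` in the truth table.
#'
#' @inheritParams simulate_rnaseq
#' @return list with `reads` (tibble `read_id`, `mate`, `seq`) and `truth`
#'   (tibble per fragment: `read_id`, `origin` in `genome`/`junction`,
#'   `chrom`, `start`, `fragment_length`).
#' @export
simulate_wgs <- function(genome, cfg, seed = 1L) {
  set.seed(seed)
  w <- cfg$wgs
  rl <- w$read_length
  lens <- chrom_lengths(genome, "sample")
  n_pairs <- rpois(1L, w$coverage * sum(lens) / (2 * rl))
  if (n_pairs == 0L) {
    return(list(
      reads = tibble(read_id = character(0), mate = integer(0), seq = character(0)),
      truth = tibble(read_id = character(0), origin = character(0),
                     chrom = character(0), start = integer(0),
                     fragment_length = integer(0))))
  }
  chrom <- sample(names(lens), n_pairs, replace = TRUE, prob = lens)
  flen <- pmax(rl + 10L, as.integer(round(rnorm(n_pairs, w$fragment_mean,
                                                w$fragment_sd))))
  flen <- pmin(flen, lens[chrom])
  start <- as.integer(floor(runif(n_pairs) * (lens[chrom] - flen + 1)))

  m1 <- unname(substring(genome$sample[chrom], start + 1L, start + rl))
  m2 <- revcomp(unname(substring(genome$sample[chrom], start + flen - rl + 1L,
                                 start + flen)))
  ids <- sprintf("wgs_%08d", seq_len(n_pairs))

  origin <- rep("genome", n_pairs)
  ins <- genome$insertions
  if (nrow(ins) > 0) {
    for (j in seq_len(nrow(ins))) {
      hit <- chrom == ins$chrom[j] &
        ((start < ins$sample_start[j] & start + flen > ins$sample_start[j]) |
         (start < ins$sample_end[j] & start + flen > ins$sample_end[j]))
      origin[hit] <- "junction"
    }
  }

  list(
    reads = tibble(
      read_id = rep(ids, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = apply_errors(c(m1, m2), cfg$error_rate)),
    truth = tibble(read_id = ids, origin = origin, chrom = chrom,
                   start = start, fragment_length = flen)
  )
}

#' Simulate a small RNA-seq library with adapter and random linkers
#'
#' Each raw read is `4 random nt + insert + 4 random nt + 3' adapter`, where
#' the insert is a consensus subsequence of a TE family (sense, or antisense
#' with the configured probability) with length drawn from the configured
#' 19-31 nt distribution. Processing must strip the adapter and 4 nt from
#' each end to recover the insert.
#'
#' @inheritParams simulate_rnaseq
#' @param n_reads number of reads.
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   `read_id`, `family`, `orientation` in `sense`/`antisense`,
#'   `insert_length`, `insert`).
#' @export
simulate_smallrna <- function(genome, cfg, n_reads, seed = 1L) {
  set.seed(seed)
  sr <- cfg$smallrna
  fams <- names(sr$family_fractions)
  family <- sample(fams, n_reads, replace = TRUE, prob = sr$family_fractions)
  orientation <- ifelse(runif(n_reads) < sr$antisense_fraction,
                        "antisense", "sense")
  lens <- as.integer(names(sr$length_probs))
  ilen <- sample(lens, n_reads, replace = TRUE, prob = sr$length_probs)

  cons_len <- setNames(nchar(genome$te_seqs), names(genome$te_seqs))
  start <- as.integer(floor(runif(n_reads) * unname(cons_len[family] - ilen + 1)))
  insert <- unname(substring(genome$te_seqs[family], start + 1L, start + ilen))
  anti <- orientation == "antisense"
  insert[anti] <- revcomp(insert[anti])

  rnd <- function() vapply(seq_len(n_reads), function(i)
    paste(sample(BASES, 4L, replace = TRUE), collapse = ""), "")
  raw <- paste0(rnd(), insert, rnd(), sr$adapter)
  raw <- apply_errors(raw, cfg$error_rate)
  ids <- sprintf("srna_%07d", seq_len(n_reads))
  list(
    reads = tibble(read_id = ids, seq = raw),
    truth = tibble(read_id = ids, family = family, orientation = orientation,
                   insert_length = ilen, insert = insert)
  )
}
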