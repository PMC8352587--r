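#' Simulation configuration for the embryonic TE-burst study design
#'
#' Bundles every parameter of the synthetic-data generator: a toy genome with
#' euchromatic chromosomes, one constitutive-heterochromatin block and one
#' chr4-like chromosome; a handful of TE families with full-length consensus
#' sequences; planted non-reference insertions; a developmental expression
#' profile in which one dominant family bursts to 1.7% of the transcriptome
#' (over 70% of all TE-derived reads); an insertion-centric H3K9me3 kernel
#' whose amplitude lags the expression peak and decays more slowly downstream
#' of the element; antisense-biased small RNAs of 19-31 nt with a 23-28 nt
#' mode; and paired-end WGS of the insertion-bearing genome.
#'
#' @param master_seed integer; expanded into per-library child seeds via
#'   [child_seed()] so adding a library never perturbs another.
#' @param chrom_specs tibble/data.frame with columns `name`, `length`,
#'   `class` (one of `"euchromatin"`, `"heterochromatin_block"`,
#'   `"chr4_like"`).
#' @param te_families tibble with columns `name`, `length`, `gc`.
#' @param n_insertions named integer vector, planted insertions per family.
#' @param strand_prob probability a planted insertion lies on the `+` strand.
#' @param min_spacing minimum distance (bp) between planted junctions on a
#'   chromosome, so each insertion's discordant-pair evidence is separable.
#' @param genome_gc GC fraction of the background genome.
#' @param timepoints ordered character vector of developmental timepoint
#'   labels (hours after egg laying).
#' @param expression_profile tibble `family` x `timepoint` -> `fraction` of
#'   the transcriptome in `[0, 1]`; per-timepoint fractions must sum to <= 1.
#' @param rna_read_length,chip_read_length read lengths (bp).
#' @param chip_kernel list with `E0` (peak IP/input fold at the junction,
#'   >= 1), `lambda` (upstream decay length, bp), `skew` (`s` > 0; downstream
#'   decay length is `lambda * s`), `lag` (named numeric in `[0, 1]` per
#'   timepoint scaling the kernel amplitude), `het_fold` and `chr4_fold`
#'   (constant IP enrichment of the heterochromatin block and the chr4-like
#'   chromosome).
#' @param wgs list with `fragment_mean`, `fragment_sd`, `read_length`,
#'   `coverage`.
#' @param smallrna list with `family_fractions` (named, sums to 1),
#'   `antisense_fraction` in `[0, 1]`, `length_probs` (named numeric over
#'   19..31 nt, mode in 23-28), `adapter` (3' adapter sequence).
#' @param error_rate per-base substitution probability applied to all
#'   simulated reads.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(
    master_seed = 1L,
    chrom_specs = tibble::tibble(
      name   = c("chr2L", "chr3L", "chrHet", "chr4"),
      length = c(500000L, 500000L, 100000L, 50000L),
      class  = c("euchromatin", "euchromatin", "heterochromatin_block", "chr4_like")
    ),
    te_families = tibble::tibble(
      name   = c("roo", "copia", "TE297"),
      length = c(2000L, 1500L, 1200L),
      gc     = c(0.45, 0.42, 0.40)
    ),
    n_insertions = c(roo = 18L, copia = 7L, TE297 = 5L),
    strand_prob = 0.5,
    min_spacing = 2000L,
    genome_gc = 0.42,
    timepoints = c("0-2h", "2-4h", "4-6h", "6-8h", "8-10h", "10-12h"),
    expression_profile = NULL,
    rna_read_length = 75L,
    chip_read_length = 75L,
    chip_kernel = list(
      E0 = 8, lambda = 750, skew = 3,
      lag = c("0-2h" = 0.05, "2-4h" = 0.2, "4-6h" = 0.6,
              "6-8h" = 1.0, "8-10h" = 0.8, "10-12h" = 0.6),
      het_fold = 8, chr4_fold = 5
    ),
    wgs = list(fragment_mean = 500, fragment_sd = 60,
               read_length = 150L, coverage = 30),
    smallrna = list(
      family_fractions = c(roo = 0.16, TE297 = 0.09, copia = 0.75),
      antisense_fraction = 0.8,
      length_probs = NULL,
      adapter = "AGATCGGAAGAGCACACGTCT"
    ),
    error_rate = 0) {

  chrom_specs <- tibble::as_tibble(chrom_specs)
  te_families <- tibble::as_tibble(te_families)

  if (is.null(expression_profile)) {
    expression_profile <- default_expression_profile(timepoints)
    expression_profile <- dplyr::filter(
      expression_profile, .data$family %in% te_families$name)
  }
  if (is.null(smallrna$length_probs)) {
    w <- stats::dnorm(19:31, mean = 26, sd = 1.8)
    smallrna$length_probs <- setNames(w / sum(w), as.character(19:31))
  }

  cfg <- structure(list(
    master_seed = as.integer(master_seed),
    chrom_specs = chrom_specs,
    te_families = te_families,
    n_insertions = n_insertions,
    strand_prob = strand_prob,
    min_spacing = as.integer(min_spacing),
    genome_gc = genome_gc,
    timepoints = timepoints,
    expression_profile = expression_profile,
    rna_read_length = as.integer(rna_read_length),
    chip_read_length = as.integer(chip_read_length),
    chip_kernel = chip_kernel,
    wgs = wgs,
    smallrna = smallrna,
    error_rate = error_rate
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# burst profile: dominant family peaks at 1.7% of the transcriptome and
# > 70% of TE reads at 4-6 h; others follow smaller dynamic profiles
default_expression_profile <- function(timepoints) {
  tp6 <- c("0-2h", "2-4h", "4-6h", "6-8h", "8-10h", "10-12h")
  base <- tibble::tibble(
    family = rep(c("roo", "copia", "TE297"), each = 6L),
    timepoint = rep(tp6, 3L),
    fraction = c(
      0.0005, 0.008, 0.017, 0.012, 0.007, 0.004,
      0.0002, 0.0015, 0.003, 0.0025, 0.002, 0.0015,
      0.0001, 0.001, 0.002, 0.0018, 0.0012, 0.001
    )
  )
  if (identical(timepoints, tp6)) return(base)
  # map arbitrary timepoint vectors onto the canonical six by position
  idx <- pmin(seq_along(timepoints), 6L)
  dplyr::bind_rows(lapply(seq_along(timepoints), function(i) {
    dplyr::mutate(dplyr::filter(base, .data$timepoint == tp6[idx[i]]),
                  timepoint = timepoints[i])
  }))
}

validate_sim_config <- function(cfg) {
  cs <- cfg$chrom_specs
  stopifnot(all(c("name", "length", "class") %in% names(cs)))
  if (!all(cs$class %in% c("euchromatin", "heterochromatin_block", "chr4_like")))
    abort("unknown chromosome class in chrom_specs")
  if (anyDuplicated(cs$name)) abort("duplicate chromosome names")
  tf <- cfg$te_families
  if (anyDuplicated(tf$name)) abort("duplicate TE family names")
  if (any(tf$gc < 0 | tf$gc > 1) || cfg$genome_gc < 0 || cfg$genome_gc > 1)
    abort("GC fractions must lie in [0, 1]")
  ep <- cfg$expression_profile
  if (any(ep$fraction < 0 | ep$fraction > 1))
    abort("expression fractions must lie in [0, 1]")
  per_tp <- tapply(ep$fraction, ep$timepoint, sum)
  if (any(per_tp > 1))
    abort("per-timepoint expression fractions must sum to <= 1")
  if (!all(names(cfg$n_insertions) %in% tf$name))
    abort("n_insertions names must be TE family names")
  kern <- cfg$chip_kernel
  if (kern$E0 < 1) abort("chip kernel E0 must be >= 1")
  if (kern$skew <= 0) abort("chip kernel skew must be > 0")
  if (any(kern$lag < 0 | kern$lag > 1)) abort("kernel lag scales must lie in [0, 1]")
  if (cfg$wgs$read_length >= cfg$wgs$fragment_mean)
    abort("WGS read length must be smaller than the mean fragment length")
  if (any(tf$length < 2L * cfg$wgs$read_length))
    abort("TE consensus lengths must be >= 2 x the WGS read length")
  sr <- cfg$smallrna
  if (abs(sum(sr$family_fractions) - 1) > 1e-8)
    abort("small RNA family fractions must sum to 1")
  if (sr$antisense_fraction < 0 || sr$antisense_fraction > 1)
    abort("antisense fraction must lie in [0, 1]")
  lens <- as.integer(names(sr$length_probs))
  if (any(lens < 19L | lens > 31L))
    abort("small RNA length distribution must be supported on 19..31 nt")
  if (cfg$error_rate < 0) abort("error_rate must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genome: ", nrow(x$chrom_specs), " chromosomes, ",
      sum(x$chrom_specs$length), " bp total\n", sep = "")
  cat("  TE families: ", paste(x$te_families$name, collapse = ", "), "\n", sep = "")
  cat("  planted insertions: ", sum(x$n_insertions), "\n", sep = "")
  cat("  timepoints: ", paste(x$timepoints, collapse = ", "), "\n", sep = "")
  invisible(x)
}
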