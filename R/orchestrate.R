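#' Pipeline configuration for the end-to-end study designs
#'
#' Collects the simulation config and every stage parameter with its
#' documented default: seed-and-verify `k` and mismatch cap, the 10 bp
#' coverage bin, the 10 kb enrichment window and euchromatin threshold, the
#' 0.5 rpm pseudocount, the 10 kb insertion flank, the 5 kb differential bin
#' and attribution distance, the 0.05 significance level, the 19-31 nt small
#' RNA window, and the replicate layout.
#'
#' @param sim a [sim_config()].
#' @param seed master pipeline seed (expanded per stage via [child_seed()]).
#' @param k,max_mismatches aligner surrogate parameters.
#' @param track_bin coverage bin (bp).
#' @param window,tau,psi enrichment window (bp), euchromatin threshold
#'   (log2), pseudocount (rpm).
#' @param flank insertion-matrix half-width (bp).
#' @param diff_bin differential bin size (bp).
#' @param attrib_dist attribution distance (bp).
#' @param alpha significance level on adjusted p.
#' @param top_n families reported in ranked tables.
#' @param n_replicates replicates per condition (depletion design).
#' @param n_rna_reads,n_chip_reads reads per RNA library and per ChIP
#'   library (IP and input each).
#' @param depleted_family family whose chromatin response is switched off in
#'   the treated condition (default the dominant family).
#' @param depletion_expression_fc RNA fold-change applied to the depleted
#'   family in the treated condition (default 2.5).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L, k = 21L,
                            max_mismatches = 2L, track_bin = 10L,
                            window = 10000L, tau = log2(2), psi = 0.5,
                            flank = 10000L, diff_bin = 5000L,
                            attrib_dist = 5000L, alpha = 0.05, top_n = 30L,
                            n_replicates = 3L, n_rna_reads = 50000L,
                            n_chip_reads = 50000L,
                            depleted_family = NULL,
                            depletion_expression_fc = 2.5) {
  structure(list(
    sim = sim, seed = as.integer(seed), k = as.integer(k),
    max_mismatches = as.integer(max_mismatches),
    track_bin = as.integer(track_bin), window = as.integer(window),
    tau = tau, psi = psi, flank = as.integer(flank),
    diff_bin = as.integer(diff_bin), attrib_dist = as.integer(attrib_dist),
    alpha = alpha, top_n = as.integer(top_n),
    n_replicates = as.integer(n_replicates),
    n_rna_reads = as.integer(n_rna_reads),
    n_chip_reads = as.integer(n_chip_reads),
    depleted_family = depleted_family %||% sim$te_families$name[1L],
    depletion_expression_fc = depletion_expression_fc
  ), class = "pipeline_config")
}

write_report_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    readr::write_tsv(report$tables[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(report$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run the developmental time-course design end to end
#'
#' Simulates RNA-seq and ChIP-seq (IP + input) for every configured
#' timepoint, assigns reads with the two-tier policy, quantifies per-family
#' TE transcriptome fractions, builds rpm tracks and insertion-centric
#' oriented signal matrices for the dominant family, and summarises the
#' temporal relationship: with the configured kernel lag, the timepoint of
#' maximal insertion-centric H3K9me3 trails the timepoint of maximal TE
#' expression.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory for TSV tables and a JSON summary.
#' @return list of class `timecourse_report`: `te_timecourse`,
#'   `insertion_signal` (per-timepoint mean near-junction IP rpm),
#'   `asymmetry`, `metaprofiles`, `summary` (with `rna_peak_timepoint`,
#'   `chip_peak_timepoint`, `lag_timepoints`, ...), `tables`.
#' @export
run_timecourse <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  genome <- build_genome(cfg)
  te_idx <- build_index(genome$te_seqs, k = config$k)
  gen_idx <- build_index(genome$reference, k = config$k)
  lens <- chrom_lengths(genome, "reference")
  dom <- config$depleted_family
  dom_ins <- dplyr::filter(genome$insertions, .data$family == dom)

  rpm_tables <- list()
  signal_rows <- list()
  asym_rows <- list()
  metas <- list()
  for (i in seq_along(cfg$timepoints)) {
    tp <- cfg$timepoints[i]
    rna <- simulate_rnaseq(genome, cfg, tp, config$n_rna_reads,
                           seed = child_seed(config$seed, 10L + i))
    asn <- assign_reads(rna$reads, te_idx, gen_idx,
                        max_mismatches = config$max_mismatches,
                        seed = child_seed(config$seed, 40L + i))
    rpm_tables[[tp]] <- rpm_normalize(count_features(asn))

    chip <- simulate_chip(genome, cfg, tp, config$n_chip_reads,
                          config$n_chip_reads,
                          seed = child_seed(config$seed, 70L + i))
    ip_asn <- assign_reads(chip$ip, te_idx, gen_idx,
                           max_mismatches = config$max_mismatches,
                           seed = child_seed(config$seed, 100L + i))
    ip_track <- coverage_track(ip_asn, lens, bin_size = config$track_bin)
    sm <- insertion_matrix(ip_track, dom_ins, flank = config$flank)
    mp <- metaprofile(sm)
    metas[[tp]] <- dplyr::mutate(mp, timepoint = tp)
    # near-junction signal: mean within one decay length of the junction
    core <- abs(mp$offset) <= cfg$chip_kernel$lambda
    signal_rows[[tp]] <- tibble(
      timepoint = tp, mean_signal = mean(mp$mean[core]))
    asym <- asymmetry_score(sm, psi = config$psi)
    asym_rows[[tp]] <- tibble(timepoint = tp,
                              median_ratio = median(asym$ratio))
  }

  tc <- te_fraction_timecourse(rpm_tables, top_n = config$top_n)
  insertion_signal <- dplyr::bind_rows(signal_rows)
  asymmetry <- dplyr::bind_rows(asym_rows)

  rna_peak <- which.max(tc$total$te_pct[match(cfg$timepoints,
                                              tc$total$timepoint)])
  chip_peak <- which.max(insertion_signal$mean_signal)
  summary <- list(
    timepoints = cfg$timepoints,
    dominant_family = dom,
    peak_te_pct = max(tc$total$te_pct),
    dominant_share_at_peak_pct = with(
      dplyr::filter(tc$by_family,
                    .data$timepoint == cfg$timepoints[rna_peak]),
      100 * pct[family == dom] / sum(pct)),
    rna_peak_timepoint = cfg$timepoints[rna_peak],
    chip_peak_timepoint = cfg$timepoints[chip_peak],
    lag_timepoints = chip_peak - rna_peak,
    median_asymmetry_at_chip_peak =
      asymmetry$median_ratio[chip_peak],
    seed = config$seed)

  report <- structure(list(
    te_timecourse = tc,
    insertion_signal = insertion_signal,
    asymmetry = asymmetry,
    metaprofiles = dplyr::bind_rows(metas),
    genome = genome,
    summary = summary,
    tables = list(
      te_timecourse_total = tc$total,
      te_timecourse_by_family = tc$by_family,
      insertion_signal = insertion_signal,
      asymmetry = asymmetry)
  ), class = "timecourse_report")
  if (!is.null(outdir)) write_report_outputs(report, outdir)
  report
}

#' Run the maternal-depletion comparison design end to end
#'
#' Two conditions ("control" and "treated") with `n_replicates` ChIP
#' libraries each; in the treated condition the chromatin kernel is switched
#' off at the depleted family's insertions and that family's RNA expression
#' is scaled by `depletion_expression_fc`. Produces the family-level MA
#' table, the 5 kb bin differential with insertion attribution, and region
#' signal comparisons (euchromatic insertion flanks vs the heterochromatin
#' block vs the chr4-like chromosome) with Welch t-tests.
#'
#' @inheritParams run_timecourse
#' @return list of class `depletion_report`: `te_ma` (an `nb_diff`),
#'   `bin_diff` (an `nb_diff`), `attribution`, `region_tests`, `summary`,
#'   `tables`.
#' @export
run_depletion_comparison <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  if (config$n_replicates < 2L) abort("need >= 2 replicates per condition")
  genome <- build_genome(cfg)
  te_idx <- build_index(genome$te_seqs, k = config$k)
  gen_idx <- build_index(genome$reference, k = config$k)
  lens <- chrom_lengths(genome, "reference")
  dom <- config$depleted_family
  tp <- names(which.max(cfg$chip_kernel$lag))

  # treated condition: dominant family expression scaled up
  cfg_treated <- cfg
  cfg_treated$expression_profile <- cfg$expression_profile |>
    dplyr::mutate(fraction = ifelse(
      .data$family == dom,
      pmin(1, .data$fraction * config$depletion_expression_fc),
      .data$fraction))

  conditions <- c("control", "treated")
  chip_assignments <- list()
  chip_tracks <- list()
  te_counts <- NULL
  groups <- character(0)
  sidx <- 0L
  for (cond in conditions) {
    for (r in seq_len(config$n_replicates)) {
      sidx <- sidx + 1L
      nm <- paste0(cond, "_rep", r)
      groups[nm] <- cond
      ccfg <- if (cond == "treated") cfg_treated else cfg
      scale_fam <- if (cond == "treated") setNames(0, dom) else NULL
      chip <- simulate_chip(genome, ccfg, tp, config$n_chip_reads,
                            config$n_chip_reads,
                            seed = child_seed(config$seed, 200L + sidx),
                            kernel_scale_by_family = scale_fam)
      ip_asn <- assign_reads(chip$ip, te_idx, gen_idx,
                             max_mismatches = config$max_mismatches,
                             seed = child_seed(config$seed, 230L + sidx))
      chip_assignments[[nm]] <- ip_asn
      chip_tracks[[nm]] <- coverage_track(ip_asn, lens,
                                          bin_size = config$track_bin)

      rna <- simulate_rnaseq(genome, ccfg, tp, config$n_rna_reads,
                             seed = child_seed(config$seed, 260L + sidx))
      rna_asn <- assign_reads(rna$reads, te_idx, gen_idx,
                              max_mismatches = config$max_mismatches,
                              seed = child_seed(config$seed, 290L + sidx))
      fam_counts <- count_features(rna_asn,
                                   features = cfg$te_families$name)
      col <- setNames(tibble(fam_counts$count), nm)
      te_counts <- if (is.null(te_counts))
        dplyr::bind_cols(tibble(feature = fam_counts$feature), col)
      else dplyr::bind_cols(te_counts, col)
    }
  }

  te_ma <- te_differential(te_counts, groups, alpha = config$alpha)
  bins <- bin_counts(chip_assignments, lens, bin = config$diff_bin)
  bin_diff <- nb_test(bins, groups)
  attribution <- attribute_bins(bin_diff, genome$insertions,
                                D = config$attrib_dist,
                                alpha = config$alpha)

  region_sets <- list(
    euchromatic_insertions = insertion_flanks(
      dplyr::filter(genome$insertions, .data$family == dom), flank = 2000L),
    heterochromatin = dplyr::filter(genome$regions,
                                    .data$class == "heterochromatin_block"),
    chr4_like = dplyr::filter(genome$regions, .data$class == "chr4_like"))
  region_tests <- purrr::map_dfr(names(region_sets), function(nm) {
    rs <- region_mean_signal(chip_tracks, region_sets[[nm]], groups)
    dplyr::mutate(rs$test, region_set = nm, .before = 1L)
  })

  gl <- glance(bin_diff, alpha = config$alpha)
  summary <- list(
    depleted_family = dom,
    timepoint = tp,
    n_signif_down_bins = gl$n_signif_down,
    n_signif_up_bins = gl$n_signif_up,
    n_down_near_depleted = attribution$n_down_within_D[
      attribution$family == dom],
    te_ma_sig_up = sum(te_ma$class == "sig_fc" & te_ma$log2fc > 0,
                       na.rm = TRUE),
    region_p = setNames(region_tests$p_value, region_tests$region_set),
    seed = config$seed)

  report <- structure(list(
    te_ma = te_ma, bin_diff = bin_diff, attribution = attribution,
    region_tests = region_tests, genome = genome, groups = groups,
    summary = summary,
    tables = list(
      diff_te = tidy(te_ma), diff_bins = tidy(bin_diff),
      attribution = attribution, region_tests = region_tests)
  ), class = "depletion_report")
  if (!is.null(outdir)) write_report_outputs(report, outdir)
  report
}

#' @export
glance.timecourse_report <- function(x, ...) {
  s <- x$summary
  tibble(peak_te_pct = s$peak_te_pct,
         dominant_share_at_peak_pct = s$dominant_share_at_peak_pct,
         rna_peak_timepoint = s$rna_peak_timepoint,
         chip_peak_timepoint = s$chip_peak_timepoint,
         lag_timepoints = s$lag_timepoints,
         median_asymmetry_at_chip_peak = s$median_asymmetry_at_chip_peak)
}

#' @export
glance.depletion_report <- function(x, ...) {
  s <- x$summary
  tibble(n_signif_down_bins = s$n_signif_down_bins,
         n_signif_up_bins = s$n_signif_up_bins,
         n_down_near_depleted = s$n_down_near_depleted,
         te_ma_sig_up = s$te_ma_sig_up)
}
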