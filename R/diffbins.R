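#' Count genome-assigned reads in fixed genomic bins
#'
#' Each read is counted once, in the bin containing its leftmost position.
#'
#' @param assignment_list named list of [assign_reads()] tibbles, one per
#'   replicate (names become sample columns).
#' @param chrom_lengths named integer vector.
#' @param bin bin size in bp (default 5000).
#' @return tibble with `feature` (`chrom:start`), `chrom`, `start`, `end`
#'   and one integer count column per replicate.
#' @export
bin_counts <- function(assignment_list, chrom_lengths, bin = 5000L) {
  grid <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin)
    starts <- (seq_len(nb) - 1L) * bin
    tibble(chrom = ch, start = starts,
           end = pmin(starts + bin, chrom_lengths[[ch]]))
  })) |>
    dplyr::mutate(feature = paste0(.data$chrom, ":", .data$start))
  out <- dplyr::select(grid, "feature", "chrom", "start", "end")
  for (s in names(assignment_list)) {
    a <- dplyr::filter(assignment_list[[s]], .data$category == "GENOME",
                       .data$target %in% names(chrom_lengths))
    key <- paste0(a$target, ":", floor(a$pos / bin) * bin)
    tab <- table(key)
    out[[s]] <- as.integer(tab[out$feature])
    out[[s]][is.na(out[[s]])] <- 0L
  }
  out
}

# sample count columns of a bin/feature count tibble
count_cols <- function(counts) {
  setdiff(names(counts), c("feature", "chrom", "start", "end"))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (nonzero in every sample) of
#' the ratio between the sample's count and the feature's geometric mean.
#'
#' @param counts tibble with a `feature` column and one count column per
#'   sample (as from [bin_counts()]), or a numeric matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  m <- if (is.data.frame(counts))
    as.matrix(counts[, count_cols(counts), drop = FALSE]) else counts
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    abort(paste0("no feature has nonzero counts in every sample; ",
                 "filter features or use a pseudo-reference"))
  lm <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lm)
  apply(exp(lm - geo), 2L, median)
}

#' Negative-binomial Wald test per feature
#'
#' Counts are normalised by size factors; the NB dispersion is estimated per
#' feature by the method of moments, `alpha = (var - mu) / mu^2`, pooled
#' across the two groups (df-weighted), then shrunk toward the across-feature
#' mean dispersion with weight `shrink` (empirical-Bayes information sharing
#' in the DESeq2/edgeR tradition -- with 2-3 replicates per group the
#' per-feature moment estimate alone is far too noisy to calibrate a Wald
#' test) and floored at `alpha_floor`. The Wald statistic on the log2
#' fold-change (group2 over group1) uses the NB delta-method standard error
#' and a standard normal reference. Features with all-zero counts are
#' excluded (`status = "low_count_excluded"`); p-values are BH-adjusted over
#' tested features.
#'
#' @param counts tibble (as from [bin_counts()]) or matrix of raw counts.
#' @param groups factor/character of length n_samples with exactly two
#'   levels; each level needs >= 2 samples.
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param alpha_floor dispersion floor (default 1e-8).
#' @param shrink weight of the across-feature mean in the dispersion
#'   estimate, in `[0, 1]` (default 0.8).
#' @param pseudo pseudocount (normalised-count units) guarding the
#'   fold-change when one group mean is 0 (default 0.5).
#' @return object of class `nb_diff`: tibble `feature`, `base_mean`,
#'   `log2fc`, `p`, `padj`, `status` (+ bin coordinates when present), with
#'   attributes `groups`, `size_factors`.
#' @export
nb_test <- function(counts, groups, sf = NULL, alpha_floor = 1e-8,
                    shrink = 0.8, pseudo = 0.5) {
  is_df <- is.data.frame(counts)
  m <- if (is_df) as.matrix(counts[, count_cols(counts), drop = FALSE])
    else counts
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) abort("groups must have exactly two levels")
  if (any(table(groups) < 2L)) abort("each group needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2L, sf, "/")
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  n1 <- sum(g1); n2 <- sum(g2)

  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1L, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1L, var)
  base_mean <- rowMeans(norm)

  a1 <- (v1 - mu1) / mu1^2
  a2 <- (v2 - mu2) / mu2^2
  a1[!is.finite(a1)] <- 0; a2[!is.finite(a2)] <- 0
  a_feat <- pmax(((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2), 0)
  a_center <- mean(a_feat[rowSums(m) > 0])
  if (!is.finite(a_center)) a_center <- 0
  alpha <- pmax((1 - shrink) * a_feat + shrink * a_center, alpha_floor)

  log2fc <- log2((mu2 + pseudo) / (mu1 + pseudo))
  se <- sqrt((1 / (mu1 + pseudo) + alpha) / n1 +
               (1 / (mu2 + pseudo) + alpha) / n2) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))

  tested <- rowSums(m) > 0
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")

  res <- tibble(
    feature = if (is_df) counts$feature else
      rownames(m) %||% paste0("f", seq_len(nrow(m))),
    base_mean = unname(base_mean), log2fc = unname(log2fc),
    dispersion = unname(alpha), stat = unname(stat), p = unname(p),
    padj = unname(padj),
    status = unname(ifelse(tested, "tested", "low_count_excluded")))
  res$log2fc[!tested] <- NA_real_
  if (is_df && all(c("chrom", "start", "end") %in% names(counts))) {
    res$chrom <- counts$chrom; res$start <- counts$start
    res$end <- counts$end
  }
  attr(res, "groups") <- groups
  attr(res, "size_factors") <- sf
  class(res) <- c("nb_diff", class(res))
  res
}

#' Attribute significant differential bins to nearby TE insertions
#'
#' A significant bin is "near" family F iff the minimum distance between the
#' bin interval and any F junction interval is at most `D` (0 for overlap;
#' boundary-inclusive). Bins near several families count for each.
#'
#' @param diff an [nb_test()] result carrying bin coordinates.
#' @param insertions tibble with `chrom`, `family` and either
#'   `start`/`end` or `pos` (junction point).
#' @param D attribution distance in bp (default 5000).
#' @param alpha significance threshold (default 0.05).
#' @param p_col `"padj"` (default) or `"p"` -- both usages are common.
#' @return tibble per family: `family`, `n_signif_down`, `n_signif_up`
#'   (global counts), `n_down_within_D`, `n_up_within_D`.
#' @export
attribute_bins <- function(diff, insertions, D = 5000L, alpha = 0.05,
                           p_col = c("padj", "p")) {
  p_col <- match.arg(p_col)
  if (!all(c("chrom", "start", "end") %in% names(diff)))
    abort("diff must carry bin coordinates (chrom/start/end)")
  ins <- tibble::as_tibble(insertions)
  if (!"start" %in% names(ins)) {
    ins$start <- ins$pos
    ins$end <- ins$pos
  }
  pv <- diff[[p_col]]
  sig <- !is.na(pv) & pv < alpha
  down <- diff[sig & diff$log2fc < 0, ]
  up <- diff[sig & diff$log2fc > 0, ]
  near_family <- function(bins, fam) {
    fi <- ins[ins$family == fam, ]
    if (nrow(bins) == 0L || nrow(fi) == 0L) return(0L)
    sum(vapply(seq_len(nrow(bins)), function(i) {
      same <- fi$chrom == bins$chrom[i]
      if (!any(same)) return(FALSE)
      gap <- pmax(0, pmax(fi$start[same] - bins$end[i],
                          bins$start[i] - fi$end[same]))
      any(gap <= D)
    }, TRUE))
  }
  fams <- sort(unique(ins$family))
  tibble(
    family = fams,
    n_signif_down = nrow(down),
    n_signif_up = nrow(up),
    n_down_within_D = vapply(fams, function(f) near_family(down, f), 1L,
                             USE.NAMES = FALSE),
    n_up_within_D = vapply(fams, function(f) near_family(up, f), 1L,
                           USE.NAMES = FALSE))
}

#' Family-level differential TE expression with MA classes
#'
#' [nb_test()] applied to a family-level count table, plus the MA-plot class
#' labels: `"sig_fc"` (adjusted p below `alpha` and fold-change beyond
#' `2^lfc_threshold`), `"sig"`, or `"ns"`.
#'
#' @inheritParams nb_test
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param lfc_threshold absolute log2 fold-change for the strong class
#'   (default 1, i.e. 2-fold).
#' @return an `nb_diff` tibble with additional `class` and
#'   `log10_base_mean` columns.
#' @export
te_differential <- function(counts, groups, sf = NULL, alpha = 0.05,
                            lfc_threshold = 1) {
  res <- nb_test(counts, groups, sf = sf)
  res$log10_base_mean <- log10(res$base_mean + 1)
  res$class <- dplyr::case_when(
    is.na(res$padj) ~ "excluded",
    res$padj < alpha & abs(res$log2fc) > lfc_threshold ~ "sig_fc",
    res$padj < alpha ~ "sig",
    TRUE ~ "ns")
  res
}

#' @export
tidy.nb_diff <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.nb_diff <- function(x, alpha = 0.05, ...) {
  tibble(
    n_features = nrow(x),
    n_tested = sum(x$status == "tested"),
    n_excluded = sum(x$status != "tested"),
    n_signif = sum(!is.na(x$padj) & x$padj < alpha),
    n_signif_down = sum(!is.na(x$padj) & x$padj < alpha & x$log2fc < 0),
    n_signif_up = sum(!is.na(x$padj) & x$padj < alpha & x$log2fc > 0))
}
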